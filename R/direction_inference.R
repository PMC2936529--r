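#' Frequency-method direction call for one GC<->AT SNP record
#'
#' The minor allele is taken to be the derived state: a GC-class minor
#' allele means the mutation was AT -> GC, an AT-class minor allele means
#' GC -> AT, and equal counts are discarded as ties.
#'
#' @param snp One-row SNP record (as produced by [extract_snps()], which
#'   orients `allele1`/`count1` to the GC-class allele for GC<->AT SNPs).
#' @return The record with `direction_freq` set.
#' @export
infer_direction_frequency <- function(snp) {
  if (snp$snp_class != "GC_AT")
    stop("classification error: frequency direction is defined for GC<->AT SNPs only")
  snp$direction_freq <-
    if (snp$count1 == snp$count2) "tie_discarded"
    else if (snp$count1 > snp$count2) "GC_to_AT"  # GC major => AT minor/derived
    else "AT_to_GC"
  snp
}

# pairwise p-distance over columns where both strains have an unambiguous base
p_distance_matrix <- function(aln) {
  b <- aln$bases
  ok <- b %in% c("A", "C", "G", "T")
  dim(ok) <- dim(b)
  n <- nrow(b)
  d <- matrix(0, n, n, dimnames = list(aln$strain_ids, aln$strain_ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- ok[i, ] & ok[j, ]
    d[i, j] <- d[j, i] <- if (any(use)) mean(b[i, use] != b[j, use]) else 0
  }
  d
}

#' Build a clock-rooted strain tree from an alignment
#'
#' Neighbor-joining (a minimum-evolution-family method) on pairwise
#' p-distances over all alignment columns, negative branch lengths clamped
#' to zero, then rooted either at the point on any edge that minimizes the
#' variance of root-to-leaf path lengths (`"clock_variance"`, the default,
#' operationalizing molecular-clock rooting) or by midpoint rooting.
#'
#' @param aln A [codon_alignment()] with at least 3 strains.
#' @param root_method `"clock_variance"` or `"midpoint"`.
#' @param on_degenerate What to do when all sequences are identical:
#'   `"error"` (default) or `"star"` (return a star tree with a warning).
#' @return A rooted `phylo` object with attribute `root_method`.
#' @export
build_strain_tree <- function(aln, root_method = c("clock_variance", "midpoint"),
                              on_degenerate = c("error", "star")) {
  root_method <- match.arg(root_method)
  on_degenerate <- match.arg(on_degenerate)
  stopifnot(inherits(aln, "codon_alignment"))
  if (length(aln$strain_ids) < 3)
    stop("tree building needs at least 3 strains")
  d <- p_distance_matrix(aln)
  if (all(d == 0)) {
    if (on_degenerate == "error")
      stop("degenerate tree: all sequences identical")
    warning("all sequences identical: returning a star tree")
    tr <- ape::stree(length(aln$strain_ids), type = "star",
                     tip.label = aln$strain_ids)
    tr$edge.length <- rep(0, nrow(tr$edge))
    attr(tr, "root_method") <- "star"
    return(tr)
  }
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  rooted <- if (root_method == "clock_variance") clock_root(tr)
            else phangorn_midpoint(tr)
  attr(rooted, "root_method") <- root_method
  rooted
}

phangorn_midpoint <- function(tr) {
  if (requireNamespace("phangorn", quietly = TRUE))
    return(phangorn::midpoint(tr))
  clock_root(tr)  # variance-minimizing root is the midpoint generalization
}

# root an unrooted phylo at the edge position minimizing the variance of
# root-to-leaf path lengths; closed-form quadratic minimum per edge
clock_root <- function(tr) {
  ntip <- length(tr$tip.label)
  dn <- ape::dist.nodes(tr)
  best <- NULL
  for (e in seq_len(nrow(tr$edge))) {
    u <- tr$edge[e, 1]; v <- tr$edge[e, 2]; L <- tr$edge.length[e]
    leaves <- seq_len(ntip)
    on_v <- dn[leaves, u] >= dn[leaves, v] + L - 1e-12
    # root at distance t from u: leaf depth = dn[leaf,v] + (L - t) on the v
    # side, dn[leaf,u] + t on the u side => depth = base + s*t
    base <- ifelse(on_v, dn[leaves, v] + L, dn[leaves, u])
    s <- ifelse(on_v, -1, 1)
    vs <- stats::var(s)
    t_star <- if (vs > 0) -stats::cov(base, s) / vs else 0
    t_star <- min(max(t_star, 0), L)
    obj <- stats::var(base + s * t_star)
    if (is.null(best) || obj < best$obj)
      best <- list(obj = obj, v = v, t = t_star, L = L)
  }
  pos <- best$t
  if (best$L > 0) pos <- min(max(pos, best$L * 1e-8), best$L * (1 - 1e-8))
  rooted <- phytools::reroot(tr, node.number = best$v, position = pos)
  rooted
}

# Fitch bottom-up pass: state set at the root of a rooted tree, given tip
# states as a named character vector; generalized to multifurcations by
# sequential pairwise intersection/union
fitch_root_states <- function(tree, tip_states) {
  if (!all(tree$tip.label %in% names(tip_states)))
    stop("input error: tree leaves do not match the provided strain states")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  sets <- vector("list", nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tip_states[[tree$tip.label[i]]]
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; child <- po$edge[e, 2]
    if (is.null(sets[[par]])) {
      sets[[par]] <- sets[[child]]
    } else {
      inter <- intersect(sets[[par]], sets[[child]])
      sets[[par]] <- if (length(inter)) inter else union(sets[[par]], sets[[child]])
    }
  }
  root <- setdiff(po$edge[, 1], po$edge[, 2])
  sets[[root[1]]]
}

#' Parsimony direction call for one GC<->AT SNP
#'
#' Runs a Fitch bottom-up pass over the rooted strain tree on the SNP's
#' column. If the root state set is a single allele, that allele is the
#' ancestral state and the direction follows (ancestral GC-class allele
#' means GC -> AT); if the root set holds both alleles the call is
#' `ambiguous` and the SNP is excluded from parsimony-based counts.
#'
#' @param tree Rooted `phylo` from [build_strain_tree()].
#' @param snp One-row GC<->AT SNP record.
#' @param column Named character vector of third-position alleles, one per
#'   strain (names = strain ids matching the tree's tip labels).
#' @return The record with `direction_parsimony` set.
#' @export
infer_direction_parsimony <- function(tree, snp, column) {
  if (snp$snp_class != "GC_AT")
    stop("classification error: parsimony direction is defined for GC<->AT SNPs only")
  root_set <- fitch_root_states(tree, column)
  snp$direction_parsimony <-
    if (length(root_set) > 1) "ambiguous"
    else if (root_set %in% c("C", "G")) "GC_to_AT"
    else "AT_to_GC"
  snp
}

#' Fill parsimony direction calls for all GC<->AT SNPs of a gene
#'
#' @param aln The [codon_alignment()] the SNPs came from.
#' @param snps SNP table from [extract_snps()].
#' @param tree Rooted strain tree; built from `aln` when omitted.
#' @return The SNP table with `direction_parsimony` filled for GC<->AT rows.
#' @export
add_parsimony_directions <- function(aln, snps, tree = NULL) {
  if (nrow(snps) == 0) return(snps)
  if (is.null(tree)) tree <- build_strain_tree(aln)
  for (r in which(snps$snp_class == "GC_AT")) {
    col <- aln$bases[, 3L * snps$codon_index[r]]
    names(col) <- aln$strain_ids
    snps[r, ] <- infer_direction_parsimony(tree, snps[r, , drop = FALSE], col)
  }
  snps
}
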