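# codon contexts used by the generators: fourfold third positions are fully
# synonymous; twofold contexts have one synonymous transition pair
# (one GC-class and one AT-class member), so both site classes carry the
# biallelic GC<->AT system of the stationary theory
.fourfold_templates <- c("GG", "GC", "CC", "GT", "AC", "TC", "CT", "CG")
.twofold_templates  <- c("AA", "GA", "CA", "TT", "AG")
# synonymous pair at a twofold context: purine contexts pair A/G, pyrimidine
# contexts pair T/C
twofold_pair <- function(context) {
  if (substr(context, 2, 2) %in% c("T", "C")) c(at = "T", gc = "C")
  else c(at = "A", gc = "G")
}

#' Specification for a synthetic dataset
#'
#' @param params A [theory_params()] giving the stationary sampling model.
#' @param n_4fold_sites,n_2fold_sites Numbers of fourfold and twofold codon
#'   columns to simulate.
#' @param seed Mandatory integer seed; identical specs give identical data.
#' @param codon_templates Optional list with elements `fourfold` and
#'   `twofold` (character vectors of two-base contexts).
#' @param recombination Optional list `(breakpoint_site, donor_divergence)`
#'   for [simulate_recombinant()]; `breakpoint_site` is a codon index.
#' @param tree Optional list `(n_taxa, height)` for
#'   [simulate_tree_alignment()] (Yule topology scaled to the given height
#'   in expected substitutions per site at the fastest class).
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(params, n_4fold_sites, n_2fold_sites = 0,
                            seed, codon_templates = NULL,
                            recombination = NULL, tree = NULL) {
  stopifnot(inherits(params, "theory_params"))
  if (missing(seed)) stop("seed is mandatory for reproducible simulation")
  if (is.null(codon_templates))
    codon_templates <- list(fourfold = .fourfold_templates,
                            twofold = .twofold_templates)
  structure(list(params = params, n_4fold_sites = n_4fold_sites,
                 n_2fold_sites = n_2fold_sites, seed = as.integer(seed),
                 codon_templates = codon_templates,
                 recombination = recombination, tree = tree),
            class = "simulation_spec")
}

#' Simulate a stationary codon alignment
#'
#' Sites are independent (free recombination, matching the independent-site
#' structure of the stationary theory). At each fourfold site the GC-class
#' allele count `i` is drawn from the sampling spectrum [sample_pmf()]; the
#' GC class is realized as C or G and the AT class as A or T (uniformly; the
#' theory collapses alleles to classes, so the split is immaterial), and the
#' GC-class allele is assigned to a uniformly random subset of `i` strains.
#' Twofold sites use the synonymous transition pair of their context. No
#' variation outside GC<->AT is introduced.
#'
#' @param spec A [simulation_spec()].
#' @param species,gene Labels for the returned alignment.
#' @return A [codon_alignment()] with attribute `truth`: data frame of
#'   `codon_index`, `degeneracy`, `true_i` (GC-class count drawn).
#' @export
simulate_alignment <- function(spec, species = "sim_species", gene = "sim_gene") {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  p <- spec$params
  n <- p$n
  pmf <- sample_pmf(p)$probs
  n4 <- spec$n_4fold_sites; n2 <- spec$n_2fold_sites
  total <- n4 + n2
  bases <- matrix("", nrow = n, ncol = 3 * total)
  truth <- data.frame(codon_index = seq_len(total),
                      degeneracy = rep(c("fourfold", "twofold"), c(n4, n2)),
                      true_i = integer(total))
  draw_i <- sample.int(length(pmf), total, replace = TRUE, prob = pmf) - 1L
  for (j in seq_len(total)) {
    four <- j <= n4
    ctx <- if (four) sample(spec$codon_templates$fourfold, 1)
           else sample(spec$codon_templates$twofold, 1)
    if (four) {
      gc_allele <- sample(c("C", "G"), 1)
      at_allele <- sample(c("A", "T"), 1)
    } else {
      pr <- twofold_pair(ctx)
      gc_allele <- pr[["gc"]]; at_allele <- pr[["at"]]
    }
    i <- draw_i[j]
    col <- rep(at_allele, n)
    if (i > 0) col[sample.int(n, i)] <- gc_allele
    bases[, (3 * j - 2):(3 * j)] <- cbind(substr(ctx, 1, 1), substr(ctx, 2, 2), col)
    truth$true_i[j] <- i
  }
  aln <- codon_alignment(bases, species = species, gene = gene,
                         strain_ids = sprintf("strain%02d", seq_len(n)))
  attr(aln, "truth") <- truth
  aln
}

#' Simulate an alignment down a known tree under infinite sites
#'
#' Generates a Yule topology, scales it to the requested height, and places
#' at most one GC<->AT mutation per fourfold site on a branch chosen
#' proportionally to its length. The per-site mutation probability is
#' `1 - exp(-r T)` with `T` the total tree length and `r = theta (1 - f)`
#' for sites whose root state is GC (loss) or `r = theta f` for AT-root
#' sites (gain), so the mutation flux matches the stationary rates. Every
#' planted SNP's true direction is recorded.
#'
#' @param spec A [simulation_spec()] with a `tree` component.
#' @param species,gene Labels.
#' @return List with `aln` (a [codon_alignment()]), `tree` (the true rooted
#'   `phylo`), and `truth` (data frame: `codon_index`, `true_direction`,
#'   `true_ancestral`, `derived_count`).
#' @export
simulate_tree_alignment <- function(spec, species = "sim_species",
                                    gene = "sim_gene") {
  stopifnot(inherits(spec, "simulation_spec"), !is.null(spec$tree))
  set.seed(spec$seed)
  p <- spec$params
  ntaxa <- spec$tree$n_taxa
  height <- spec$tree$height
  tr <- ape::rphylo(ntaxa, birth = 1, death = 0)
  tr$edge.length <- tr$edge.length * (height / max(ape::node.depth.edgelength(tr)))
  tr$tip.label <- sprintf("strain%02d", seq_len(ntaxa))
  Ttot <- sum(tr$edge.length)
  n4 <- spec$n_4fold_sites
  rate_gc <- p$theta * (1 - p$f)   # loss rate at GC-root sites
  rate_at <- p$theta * p$f
  # the generator places at most one mutation per site by construction, but
  # once the requested pressure implies several mutations per site the
  # truncation badly misrepresents the asked-for process
  if (max(rate_gc, rate_at) * Ttot > 3)
    stop("infinite-sites violation: the requested mutation pressure implies ",
         "multiple mutations per site; reduce theta or the tree height")
  # tip membership below each edge
  tips_below <- lapply(seq_len(nrow(tr$edge)), function(e) {
    nd <- tr$edge[e, 2]
    if (nd <= ntaxa) nd else
      intersect(unlist(ape::prop.part(tr)[[nd - ntaxa]]), seq_len(ntaxa))
  })
  bases <- matrix("", nrow = ntaxa, ncol = 3 * n4)
  truth_rows <- list()
  for (j in seq_len(n4)) {
    ctx <- sample(spec$codon_templates$fourfold, 1)
    root_gc <- stats::runif(1) < p$f
    anc_allele <- if (root_gc) sample(c("C", "G"), 1) else sample(c("A", "T"), 1)
    der_allele <- if (root_gc) sample(c("A", "T"), 1) else sample(c("C", "G"), 1)
    r <- if (root_gc) rate_gc else rate_at
    col <- rep(anc_allele, ntaxa)
    if (Ttot > 0 && stats::runif(1) < 1 - exp(-r * Ttot)) {
      e <- sample.int(nrow(tr$edge), 1, prob = tr$edge.length)
      idx <- tips_below[[e]]
      col[idx] <- der_allele
      if (length(idx) > 0 && length(idx) < ntaxa)
        truth_rows[[length(truth_rows) + 1]] <- data.frame(
          codon_index = j,
          true_direction = if (root_gc) "GC_to_AT" else "AT_to_GC",
          true_ancestral = anc_allele,
          derived_count = length(idx))
    }
    bases[, (3 * j - 2):(3 * j)] <-
      cbind(substr(ctx, 1, 1), substr(ctx, 2, 2), col)
  }
  aln <- codon_alignment(bases, species = species, gene = gene,
                         strain_ids = tr$tip.label)
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(codon_index = integer(), true_direction = character(),
               true_ancestral = character(), derived_count = integer())
  list(aln = aln, tree = tr, truth = truth)
}

#' Simulate a recombinant (mosaic) alignment
#'
#' Draws a stationary alignment, then replaces the first strain's third
#' positions left of the breakpoint with a diverged donor haplotype: each
#' such site switches to an allele of the opposite GC class with probability
#' `donor_divergence`. With sufficient divergence and background
#' polymorphism this plants a mosaic detectable by [maxchi_test()] and
#' four-gamete-violating site pairs.
#'
#' @param spec A [simulation_spec()] with a `recombination` component
#'   (`breakpoint_site` = codon index of the last donor codon,
#'   `donor_divergence` in \[0, 1\]).
#' @param species,gene Labels.
#' @return A [codon_alignment()] with attribute `truth_breakpoint` (the
#'   planted codon index) and `recombinant_strain`.
#' @export
simulate_recombinant <- function(spec, species = "sim_species",
                                 gene = "sim_gene") {
  stopifnot(inherits(spec, "simulation_spec"), !is.null(spec$recombination))
  bp <- spec$recombination$breakpoint_site
  div <- spec$recombination$donor_divergence
  total <- spec$n_4fold_sites + spec$n_2fold_sites
  if (bp < 1 || bp >= total)
    stop("input error: breakpoint_site must lie inside the alignment")
  aln <- simulate_alignment(spec, species = species, gene = gene)
  flip <- c(A = "G", T = "C", G = "A", C = "T")  # swap GC class, keep ts pairing
  for (j in seq_len(bp)) {
    pos <- 3 * j
    if (stats::runif(1) < div)
      aln$bases[1, pos] <- flip[[aln$bases[1, pos]]]
  }
  attr(aln, "truth_breakpoint") <- bp
  attr(aln, "recombinant_strain") <- aln$strain_ids[1]
  aln
}

#' Simulate a cohort of species with known parameters
#'
#' Per-species equilibrium GC `f` and scaled rate `theta` are drawn
#' uniformly from the given ranges; selection can be constant, per-species,
#' or a function of `f` (to plant a selection-with-GC-content association).
#'
#' @param n_species Number of species.
#' @param f_range,theta_range Length-2 ranges for uniform draws.
#' @param S_per_species Scalar, vector of length `n_species`, or
#'   `function(f)` returning S.
#' @param n_strains Strains per species.
#' @param n_sites Fourfold sites per species (one gene per species).
#' @param seed Integer seed.
#' @return List of per-species lists `(spec, aln)`.
#' @export
simulate_cohort <- function(n_species, f_range = c(0.2, 0.8),
                            theta_range = c(0.01, 0.05), S_per_species = 0,
                            n_strains = 10, n_sites = 2000, seed = 1) {
  set.seed(seed)
  fs <- stats::runif(n_species, f_range[1], f_range[2])
  thetas <- stats::runif(n_species, theta_range[1], theta_range[2])
  Ss <- if (is.function(S_per_species)) vapply(fs, S_per_species, numeric(1))
        else rep_len(S_per_species, n_species)
  seeds <- sample.int(.Machine$integer.max - 1L, n_species)
  lapply(seq_len(n_species), function(k) {
    sp <- simulation_spec(theory_params(thetas[k], fs[k], Ss[k], n_strains),
                          n_4fold_sites = n_sites, seed = seeds[k])
    list(spec = sp,
         aln = simulate_alignment(sp, species = sprintf("species%03d", k),
                                  gene = "gene1"))
  })
}
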