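#' Construct a codon alignment object
#'
#' A `codon_alignment` holds an in-frame aligned set of protein-coding
#' sequences from conspecific strains as a strain x position character
#' matrix. All downstream operations (site classification, SNP extraction,
#' diversity, trees, screens) take this object.
#'
#' @param bases Character matrix of single upper-case characters
#'   (`A,C,G,T,-,N`), rows = strains, columns = alignment positions. The
#'   number of columns must be divisible by 3.
#' @param species,gene Labels carried through to reports.
#' @param strain_ids Optional strain names; defaults to the matrix rownames.
#' @return An object of class `codon_alignment` with elements `species`,
#'   `gene`, `strain_ids`, `bases`, `n_codons`.
#' @export
codon_alignment <- function(bases, species = "", gene = "", strain_ids = rownames(bases)) {
  if (!is.matrix(bases) || !is.character(bases))
    stop("`bases` must be a character matrix of single characters")
  if (nrow(bases) < 2)
    stop("a codon alignment needs at least 2 strains")
  if (ncol(bases) %% 3L != 0L)
    stop("frame error: alignment length ", ncol(bases), " is not divisible by 3")
  if (is.null(strain_ids)) strain_ids <- paste0("strain", seq_len(nrow(bases)))
  bases <- toupper(bases)
  bad <- !(bases %in% c("A", "C", "G", "T", "-", "N"))
  if (any(bad)) bases[bad] <- "N"
  rownames(bases) <- strain_ids
  structure(
    list(species = species, gene = gene, strain_ids = strain_ids,
         bases = bases, n_codons = ncol(bases) %/% 3L),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", x$species, "/", x$gene, "-",
      length(x$strain_ids), "strains x", x$n_codons, "codons\n")
  invisible(x)
}

#' Read an in-frame codon alignment from aligned FASTA
#'
#' @param path Path to an aligned FASTA file; all sequences must have equal
#'   length divisible by 3.
#' @param species,gene Labels attached to the returned object.
#' @return A [codon_alignment()] with strain order as in the file.
#' @export
read_codon_alignment <- function(path, species = "", gene = "") {
  dna <- ape::read.FASTA(path)
  if (length(dna) < 2) stop("format error: fewer than 2 sequences in ", path)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L)
    stop("format error: ragged alignment in ", path,
         " (lengths ", paste(unique(lens), collapse = ","), ")")
  if (lens[1] %% 3L != 0L)
    stop("frame error: alignment length ", lens[1], " not divisible by 3 in ", path)
  m <- toupper(as.character(as.matrix(dna)))
  codon_alignment(m, species = species, gene = gene, strain_ids = names(dna))
}

#' Write a codon alignment to FASTA
#'
#' @param aln A [codon_alignment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_codon_alignment <- function(aln, path) {
  dna <- ape::as.DNAbin(aln$bases)
  ape::write.FASTA(dna, path)
  invisible(path)
}

# codon -> amino acid lookup for an NCBI genetic code id; "*" marks stops.
# cached per code id
.gc_code_cache <- new.env(parent = emptyenv())

genetic_code_table <- function(code = 11) {
  key <- as.character(code)
  if (!is.null(.gc_code_cache[[key]])) return(.gc_code_cache[[key]])
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  aa <- vapply(codons, function(cd) {
    out <- tryCatch(
      seqinr::translate(strsplit(cd, "")[[1]], numcode = code),
      error = function(e) NA_character_)
    if (is.na(out) || out == "X")  # translate yields X for unknown code ids
      stop("configuration error: unknown genetic code id ", code)
    out
  }, character(1))
  tab <- stats::setNames(aa, codons)
  .gc_code_cache[[key]] <- tab
  tab
}

# degeneracy of a two-base codon context under a code table:
# "fourfold" if NN1..NN4 all encode one amino acid, "twofold" if the four
# third bases split into exactly two synonymous transition pairs
# (pyrimidine pair vs purine pair), otherwise "other"
context_degeneracy <- function(context, code_tab) {
  third <- c("T", "C", "A", "G")
  aa <- unname(code_tab[paste0(context, third)])
  if (length(unique(aa)) == 1L) return("fourfold")
  if (length(unique(aa)) == 2L && aa[1] == aa[2] && aa[3] == aa[4])
    return("twofold")  # pyrimidine pair vs purine pair (transition pairs)
  "other"
}

#' Classify third-position degeneracy of every codon column
#'
#' A codon column is classified from the genetic code given its (shared)
#' first two positions: `fourfold` if all four third-position bases encode
#' the same amino acid, `twofold` if the third bases split into two
#' synonymous transition pairs, `other` for remaining patterns. A column is
#' `invalid` when any strain has a gap or ambiguity anywhere in the codon,
#' when the first two positions vary across strains, or when the observed
#' codons encode more than one amino acid (so that third-position changes
#' would not be synonymous in every strain).
#'
#' @param aln A [codon_alignment()].
#' @param code NCBI genetic code id (default 11, the bacterial code, whose
#'   degeneracy structure matches the standard code).
#' @return A data frame with one row per codon column: `codon_index`
#'   (1-based), `degeneracy`, `context` (first two positions, `NA` when
#'   invalid).
#' @export
classify_sites <- function(aln, code = 11) {
  stopifnot(inherits(aln, "codon_alignment"))
  code_tab <- genetic_code_table(code)
  nc <- aln$n_codons
  n <- nrow(aln$bases)
  b1 <- aln$bases[, seq.int(1L, 3L * nc, by = 3L), drop = FALSE]
  b2 <- aln$bases[, seq.int(2L, 3L * nc, by = 3L), drop = FALSE]
  b3 <- aln$bases[, seq.int(3L, 3L * nc, by = 3L), drop = FALSE]
  acgt <- c("A", "C", "G", "T")
  clean <- matrix(b1 %in% acgt & b2 %in% acgt & b3 %in% acgt, n, nc)
  all_clean <- colSums(clean) == n
  const12 <- colSums(b1 != b1[rep(1L, n), , drop = FALSE]) == 0 &
    colSums(b2 != b2[rep(1L, n), , drop = FALSE]) == 0
  # amino acid must be identical across strains (third-position changes
  # synonymous in every strain)
  aa <- matrix(unname(code_tab[paste0(b1, b2, b3)]), n, nc)
  same_aa <- colSums(aa != aa[rep(1L, n), , drop = FALSE]) == 0
  same_aa[is.na(same_aa)] <- FALSE
  valid <- all_clean & const12 & same_aa
  degeneracy <- rep("invalid", nc)
  context <- rep(NA_character_, nc)
  if (any(valid)) {
    ctx <- paste0(b1[1L, valid], b2[1L, valid])
    deg16 <- vapply(unique(ctx), context_degeneracy, character(1),
                    code_tab = code_tab)
    degeneracy[valid] <- deg16[ctx]
    context[valid] <- ctx
  }
  data.frame(codon_index = seq_len(nc), degeneracy = degeneracy,
             context = context, stringsAsFactors = FALSE)
}

.GC <- c("C", "G")
.AT <- c("A", "T")

snp_class_of <- function(a1, a2) {
  g1 <- a1 %in% .GC; g2 <- a2 %in% .GC
  if (g1 != g2) "GC_AT" else if (g1) "GC_GC" else "AT_AT"
}

#' Extract biallelic third-position SNPs
#'
#' Scans fourfold and twofold codon columns for third-position
#' polymorphisms. Sites with more than two alleles are discarded entirely.
#' Biallelic GC<->AT sites with the two alleles at equal frequency are kept
#' as records but marked `tie_discarded` (they contribute to neither U nor
#' V). GC<->GC and AT<->AT SNPs are flagged `not_gc_at`. The frequency
#' direction call (minor allele = derived) is filled in for GC<->AT SNPs.
#'
#' @param aln A [codon_alignment()].
#' @param sites Site classification from [classify_sites()] on the same
#'   alignment.
#' @return A data frame of SNP records with columns `species`, `gene`,
#'   `codon_index`, `degeneracy`, `allele1`, `count1`, `allele2`, `count2`
#'   (allele1 is the GC-class allele for GC<->AT SNPs, else the major
#'   allele), `snp_class`, `direction_freq`, `direction_parsimony`
#'   (initially `not_evaluated`), `singleton`.
#' @export
extract_snps <- function(aln, sites) {
  stopifnot(inherits(aln, "codon_alignment"))
  keep <- which(sites$degeneracy %in% c("fourfold", "twofold"))
  if (length(keep) == 0L) return(empty_snp_table())
  third <- aln$bases[, 3L * keep, drop = FALSE]
  acgt <- c("A", "C", "G", "T")
  counts <- vapply(acgt, function(b) colSums(third == b),
                   numeric(length(keep)))
  if (length(keep) == 1L) counts <- matrix(counts, nrow = 1)
  biall <- rowSums(counts > 0) == 2L
  keep <- keep[biall]                 # monomorphic or >2 alleles: no record
  if (length(keep) == 0L) return(empty_snp_table())
  counts <- counts[biall, , drop = FALSE]
  i1 <- max.col(counts > 0, ties.method = "first")
  i2 <- max.col(counts > 0, ties.method = "last")
  a1 <- acgt[i1]; a2 <- acgt[i2]
  c1 <- counts[cbind(seq_along(i1), i1)]
  c2 <- counts[cbind(seq_along(i2), i2)]
  gc1 <- a1 %in% .GC; gc2 <- a2 %in% .GC
  cls <- ifelse(gc1 != gc2, "GC_AT", ifelse(gc1, "GC_GC", "AT_AT"))
  # orient allele1 to the GC-class allele for GC<->AT SNPs, to the major
  # allele otherwise
  swap <- (cls == "GC_AT" & !gc1) | (cls != "GC_AT" & c1 < c2)
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  tmpc <- c1[swap]; c1[swap] <- c2[swap]; c2[swap] <- tmpc
  # allele1 is GC for GC<->AT SNPs: a GC majority means the minor (derived)
  # allele is AT, i.e. the mutation was GC->AT
  dirf <- ifelse(cls != "GC_AT", "not_gc_at",
                 ifelse(c1 == c2, "tie_discarded",
                        ifelse(c1 > c2, "GC_to_AT", "AT_to_GC")))
  data.frame(
    species = aln$species, gene = aln$gene, codon_index = keep,
    degeneracy = sites$degeneracy[keep],
    allele1 = a1, count1 = as.integer(c1),
    allele2 = a2, count2 = as.integer(c2),
    snp_class = cls, direction_freq = dirf,
    direction_parsimony = "not_evaluated",
    singleton = pmin(c1, c2) == 1L,
    stringsAsFactors = FALSE)
}

empty_snp_table <- function() {
  data.frame(species = character(), gene = character(),
             codon_index = integer(), degeneracy = character(),
             allele1 = character(), count1 = integer(),
             allele2 = character(), count2 = integer(),
             snp_class = character(), direction_freq = character(),
             direction_parsimony = character(), singleton = logical(),
             stringsAsFactors = FALSE)
}

#' GC-content and GC<->AT diversity summary over degenerate sites
#'
#' `gc4` (`gc2`) is the fraction of G or C bases pooled over all strains and
#' all valid fourfold (twofold) third positions. `pi_gc_at_4fold` is the
#' per-site heterozygosity for the GC-vs-AT allele classes,
#' `2 i (n - i) / (n (n - 1))` with `i` the number of GC-class bases at the
#' site, averaged over valid fourfold sites (monomorphic sites contribute
#' zero).
#'
#' @param aln A [codon_alignment()].
#' @param sites Classification from [classify_sites()].
#' @return A list with `pi_gc_at_4fold`, `n_4fold_sites`, `n_2fold_sites`,
#'   `gc4`, `gc2`, `n_strains`.
#' @export
diversity_summary <- function(aln, sites) {
  stopifnot(inherits(aln, "codon_alignment"))
  i4 <- which(sites$degeneracy == "fourfold")
  i2 <- which(sites$degeneracy == "twofold")
  if (length(i4) == 0L)
    stop("undefined summary: no valid fourfold sites in ",
         aln$species, "/", aln$gene)
  n <- nrow(aln$bases)
  gc_count <- function(js) {
    if (length(js) == 0L) return(NA_real_)
    third <- aln$bases[, 3L * js, drop = FALSE]
    mean(third %in% .GC)
  }
  third4 <- aln$bases[, 3L * i4, drop = FALSE]
  i_gc <- colSums(matrix(third4 %in% .GC, nrow = n))
  pi_site <- 2 * i_gc * (n - i_gc) / (n * (n - 1))
  list(pi_gc_at_4fold = mean(pi_site),
       n_4fold_sites = length(i4),
       n_2fold_sites = length(i2),
       gc4 = gc_count(i4),
       gc2 = gc_count(i2),
       n_strains = n)
}

#' Write a per-gene SNP table as TSV
#'
#' @param snps SNP table from [extract_snps()] (possibly after parsimony
#'   calls were added).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(snps, path) {
  utils::write.table(snps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
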