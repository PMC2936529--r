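# columns of the alignment that are polymorphic with exactly two unambiguous
# alleles in every strain; returns the column indices and the 0/1-coded
# allele matrix (strains x sites)
biallelic_columns <- function(aln) {
  b <- aln$bases
  keep <- integer(0)
  coded <- NULL
  for (j in seq_len(ncol(b))) {
    col <- b[, j]
    if (any(!col %in% c("A", "C", "G", "T"))) next
    u <- unique(col)
    if (length(u) != 2L) next
    keep <- c(keep, j)
    coded <- cbind(coded, as.integer(col == u[1]))
  }
  list(cols = keep, coded = coded)
}

#' Four-gamete test for recombination
#'
#' Scans every pair of biallelic sites (any site class: recombination acts
#' on the locus, not on synonymous positions) for the presence of all four
#' two-site haplotypes, which cannot arise on a single tree without
#' recurrent mutation. Deterministic; the first violating pair is recorded.
#'
#' @param aln A [codon_alignment()].
#' @return List with `fgt_violation` (flag), `fgt_witness` (alignment column
#'   pair, or `NULL`), `n_biallelic_sites`, `evaluable` (`FALSE` when fewer
#'   than two biallelic sites exist).
#' @export
four_gamete_test <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  ba <- biallelic_columns(aln)
  k <- length(ba$cols)
  if (k < 2L)
    return(list(fgt_violation = FALSE, fgt_witness = NULL,
                n_biallelic_sites = k, evaluable = FALSE))
  for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
    hap <- ba$coded[, a] * 2L + ba$coded[, b]
    if (length(unique(hap)) == 4L)
      return(list(fgt_violation = TRUE,
                  fgt_witness = c(ba$cols[a], ba$cols[b]),
                  n_biallelic_sites = k, evaluable = TRUE))
  }
  list(fgt_violation = FALSE, fgt_witness = NULL,
       n_biallelic_sites = k, evaluable = TRUE)
}

# 2x2 chi-square (no continuity correction) for every breakpoint, given the
# cumulative mismatch counts of one strain pair over K ordered sites;
# zero-margin tables score 0
maxchi_stats_for_pair <- function(cum_mismatch, K) {
  b <- seq_len(K - 1L)           # breakpoint after site b
  a11 <- cum_mismatch[b]         # left mismatches
  tot <- cum_mismatch[K]
  a21 <- b - a11                 # left matches
  a12 <- tot - a11               # right mismatches
  a22 <- (K - b) - a12
  num <- (a11 * a22 - a12 * a21)^2 * K
  den <- (a11 + a12) * (a21 + a22) * (a11 + a21) * (a12 + a22)
  ifelse(den > 0, num / den, 0)
}

# exact-tail score for the same tables: -log of the smaller hypergeometric
# tail of the left-mismatch count. Ranking tables by exact tail rather than
# by raw chi-square is the sensitivity adjustment of this implementation:
# the raw statistic reaches its ceiling (chi = K) for any table with a
# handful of mismatches that happen to sit together at one end, so ranking
# by chi lets tiny-margin flukes swamp genuine mosaics in the permutation
# null, whereas the exact tail accounts for the margins
maxchi_scores_for_pair <- function(cum_mismatch, K) {
  b <- seq_len(K - 1L)
  a11 <- cum_mismatch[b]
  tot <- cum_mismatch[K]
  if (tot == 0L) return(numeric(K - 1L))
  lo <- stats::phyper(a11, tot, K - tot, b)
  hi <- stats::phyper(a11 - 1, tot, K - tot, b, lower.tail = FALSE)
  -log(pmax(2 * pmin(lo, hi), 1e-300))
}

#' Maximum chi-squared (maxchi) test for mosaic haplotypes
#'
#' Maynard Smith's maxchi scan in the window-free, all-breakpoints variant:
#' for every strain pair, sites polymorphic in the full alignment are scored
#' match/mismatch along the pair and every breakpoint between consecutive
#' polymorphic sites is evaluated by the 2x2 (left/right x match/mismatch)
#' chi-square without continuity correction. As a sensitivity adjustment,
#' candidate tables are ranked (and the permutation null evaluated) by the
#' exact hypergeometric tail of the table rather than by the raw chi-square,
#' which hits its ceiling for any few clustered mismatches and would let
#' tiny-margin flukes swamp genuine mosaics; the chi-square of the winning
#' table is still reported. Significance of the overall maximum is assessed
#' by permuting the site order and re-maximizing over pairs and breakpoints
#' each time.
#'
#' @param aln A [codon_alignment()].
#' @param n_perm Number of site-order permutations (values below 100 give an
#'   imprecise p and raise a warning).
#' @param seed Integer seed for the permutation null.
#' @return List with `maxchi_max_stat`, `maxchi_breakpoint` (alignment
#'   column left of the best junction), `breakpoint_ordinal` (its rank among
#'   polymorphic sites), `pair` (strain ids), `maxchi_p`, `n_permutations`,
#'   `n_polymorphic_sites`, `seed`, `evaluable`, and `variant` metadata
#'   (all-breakpoints scan; the windowless form is chosen for sensitivity).
#' @export
maxchi_test <- function(aln, n_perm = 1000, seed = 1) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (n_perm > 0 && n_perm < 100)
    warning("n_perm < 100: permutation p-value is imprecise")
  ba <- biallelic_columns(aln)
  K <- length(ba$cols)
  if (K < 4L || nrow(aln$bases) < 2L)
    return(list(maxchi_max_stat = NA_real_, maxchi_breakpoint = NA_integer_,
                breakpoint_ordinal = NA_integer_, pair = NULL,
                maxchi_p = NA_real_, n_permutations = 0L,
                n_polymorphic_sites = K, seed = seed, evaluable = FALSE,
                variant = "all-breakpoints"))
  n <- nrow(aln$bases)
  pairs <- utils::combn(n, 2)
  # mismatch matrix: K sites x P pairs
  M <- apply(pairs, 2, function(pr)
    as.integer(ba$coded[pr[1], ] != ba$coded[pr[2], ]))
  scan_max <- function(ord) {
    Mo <- M[ord, , drop = FALSE]
    best <- -Inf; bp <- NA_integer_; bpair <- NA_integer_
    cum <- apply(Mo, 2, cumsum)
    for (p in seq_len(ncol(M))) {
      sc <- maxchi_scores_for_pair(cum[, p], K)
      m <- max(sc)
      if (m > best) {
        best <- m
        # the maximal score usually extends over a plateau of equivalent
        # breakpoints (no mismatch transitions inside); report its midpoint
        ties <- which(sc >= m - 1e-12)
        run <- ties[ties - ties[1] == seq_along(ties) - 1L]  # leading run
        bp <- run[ceiling(length(run) / 2)]
        bpair <- p
      }
    }
    chi <- if (!is.na(bpair)) maxchi_stats_for_pair(cum[, bpair], K)[bp] else NA_real_
    list(score = best, stat = chi, bp = bp, pair = bpair)
  }
  obs <- scan_max(seq_len(K))
  p_val <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    exceed <- 0L
    for (r in seq_len(n_perm)) {
      if (scan_max(sample.int(K))$score >= obs$score) exceed <- exceed + 1L
    }
    p_val <- (exceed + 1) / (n_perm + 1)
  }
  list(maxchi_max_stat = obs$stat,
       maxchi_breakpoint = if (!is.na(obs$bp)) ba$cols[obs$bp] else NA_integer_,
       breakpoint_ordinal = obs$bp,
       pair = if (!is.na(obs$pair)) aln$strain_ids[pairs[, obs$pair]] else NULL,
       maxchi_p = p_val, n_permutations = as.integer(n_perm),
       n_polymorphic_sites = K, seed = seed, evaluable = TRUE,
       variant = "all-breakpoints, exact-tail ranking")
}

#' Run both recombination screens on one alignment
#'
#' @param aln A [codon_alignment()].
#' @param n_perm,seed Passed to [maxchi_test()].
#' @param alpha Significance level for the maxchi exclusion flag.
#' @return List combining the [four_gamete_test()] and [maxchi_test()]
#'   reports plus `excluded_fgt` and `excluded_maxchi` flags.
#' @export
recombination_screen <- function(aln, n_perm = 1000, seed = 1, alpha = 0.05) {
  fgt <- four_gamete_test(aln)
  mx <- maxchi_test(aln, n_perm = n_perm, seed = seed)
  c(fgt, mx,
    list(excluded_fgt = isTRUE(fgt$fgt_violation),
         excluded_maxchi = isTRUE(!is.na(mx$maxchi_p) && mx$maxchi_p < alpha)))
}
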