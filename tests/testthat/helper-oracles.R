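# Independent oracles and fixture builders used across the suite.

# Build a codon_alignment from per-strain codon strings, e.g.
# make_aln(c("GGAGGC", "GGAGGT")).
make_aln <- function(seqs, species = "sp", gene = "g",
                     strain_ids = sprintf("s%02d", seq_along(seqs))) {
  m <- do.call(rbind, lapply(seqs, function(s) strsplit(s, "")[[1]]))
  codon_alignment(m, species = species, gene = gene, strain_ids = strain_ids)
}

# Quadrature oracle for the sampling spectrum: direct integration of the
# stationary kernel against binomial sampling, endpoint singularities
# removed by the substitutions x = t^(1/a) and 1 - x = t^(1/c). Written
# independently of the package's closed form (no 1F1).
quad_pmf_oracle <- function(theta, f, S, n) {
  U <- theta * (1 - f); V <- theta * f
  raw <- vapply(0:n, function(i) {
    a <- V + i; cc <- U + n - i
    left <- stats::integrate(function(t) {
      x <- t^(1 / a); (1 / a) * (1 - x)^(cc - 1) * exp(S * x)
    }, 0, 0.5^a, rel.tol = 1e-12, abs.tol = 0)$value
    right <- stats::integrate(function(t) {
      x <- 1 - t^(1 / cc); (1 / cc) * x^(a - 1) * exp(S * x)
    }, 0, 0.5^cc, rel.tol = 1e-12, abs.tol = 0)$value
    choose(n, i) * (left + right)
  }, numeric(1))
  raw / sum(raw)
}

# Forward Wright-Fisher oracle: simulates N haploid individuals per site
# with reversible GC<->AT mutation at matched scaled rates (and optional
# genic selection), then samples n copies per site; returns the empirical
# pmf of GC counts with per-class standard errors.
wf_pmf_oracle <- function(theta, f, S, n, N = 200, n_sites = 20000,
                          burnin_N = 12, seed = 1) {
  set.seed(seed)
  u <- theta * (1 - f) / (2 * N)
  v <- theta * f / (2 * N)
  s <- S / (2 * N)
  # start sites monomorphic with the stationary boundary occupancy: at low
  # theta the chain flips between fixed states at rates (mutation influx x
  # Kimura fixation probability), which mix far more slowly than the
  # interior relaxes, so the initial occupancy must already be right
  pfix <- function(sel) if (sel == 0) 1 / N else
    (1 - exp(-2 * sel)) / (1 - exp(-2 * N * sel))
  r_at_to_gc <- v * N * pfix(s)
  r_gc_to_at <- u * N * pfix(-s)
  p_gc0 <- r_at_to_gc / (r_at_to_gc + r_gc_to_at)
  x <- ifelse(stats::runif(n_sites) < p_gc0, N, 0L)
  for (g in seq_len(burnin_N * N)) {
    p <- x / N
    p <- p * (1 + s) / (p * (1 + s) + (1 - p))
    p <- p * (1 - u) + (1 - p) * v
    x <- stats::rbinom(n_sites, N, p)
  }
  i <- stats::rhyper(n_sites, x, N - x, n)
  counts <- tabulate(i + 1L, n + 1L)
  pmf <- counts / n_sites
  list(pmf = pmf, se = sqrt(pmf * (1 - pmf) / n_sites))
}

# empirical Z (frequency method) and its binomial se from a SNP table
observed_z <- function(snps, degeneracy = "fourfold") {
  d <- snps[snps$snp_class == "GC_AT" & snps$degeneracy == degeneracy &
              snps$direction_freq %in% c("GC_to_AT", "AT_to_GC"), ]
  k <- sum(d$direction_freq == "GC_to_AT"); m <- nrow(d)
  list(z = k / m, se = sqrt(0.25 / m), n = m)
}
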