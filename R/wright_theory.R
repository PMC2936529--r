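#' Parameters of the Wright stationary model
#'
#' The model treats a degenerate third codon position as a biallelic
#' GC-vs-AT system in a haploid population of constant size. With scaled
#' total mutation rate `theta` = 2 N_e mu, equilibrium GC fraction under
#' mutation alone `f` = v/(u+v), and scaled selection `S` = 2 N_e s
#' favouring GC when positive, the scaled directional rates are
#' `U = theta (1 - f)` (GC -> AT) and `V = theta f` (AT -> GC).
#'
#' @param theta Scaled total GC<->AT mutation rate, > 0. Under
#'   `rate_model = "exponential"` this is the mean of the per-site
#'   exponential rate distribution.
#' @param f Equilibrium GC fraction in (0, 1).
#' @param S Scaled selection coefficient (default 0).
#' @param n Sample size (number of strains), >= 2.
#' @param rate_model `"constant"` or `"exponential"` (per-site rates
#'   exponentially distributed with mean `theta`).
#' @return An object of class `theory_params`.
#' @export
theory_params <- function(theta, f, S = 0, n = 10,
                          rate_model = c("constant", "exponential")) {
  rate_model <- match.arg(rate_model)
  if (!is.numeric(theta) || theta <= 0)
    stop("parameter error: theta must be > 0")
  if (!is.numeric(f) || f <= 0 || f >= 1)
    stop("parameter error: f must lie in (0, 1)")
  if (!is.numeric(n) || n < 2 || n != round(n))
    stop("parameter error: n must be an integer >= 2")
  structure(list(theta = theta, f = f, S = S, n = as.integer(n),
                 U = theta * (1 - f), V = theta * f,
                 rate_model = rate_model),
            class = "theory_params")
}

#' @export
print.theory_params <- function(x, ...) {
  cat(sprintf("theory_params: theta=%g f=%g S=%g n=%d (%s rates)\n",
              x$theta, x$f, x$S, x$n, x$rate_model))
  invisible(x)
}

# log of Kummer's confluent hypergeometric 1F1(a; b; s), a > 0, b > a.
# Series in the stable direction (Kummer transform for s < 0); for s > 50
# the series is abandoned for quadrature of the integral representation
# 1F1(a;b;s) = \int x^{a-1}(1-x)^{b-a-1} e^{sx} dx / B(a, b-a),
# evaluated in log space with the e^s factor pulled out.
log1F1 <- function(a, b, s, max_terms = 5000L) {
  stopifnot(a > 0, b > a)
  if (s == 0) return(structure(0, method = "series"))
  if (s < 0) {
    out <- log1F1(b - a, b, -s, max_terms)  # Kummer: 1F1(a;b;s)=e^s 1F1(b-a;b;-s)
    return(structure(s + as.numeric(out), method = attr(out, "method")))
  }
  if (s <= 50) {
    term <- 1; total <- 1
    for (k in 0:max_terms) {
      term <- term * (a + k) / (b + k) * s / (k + 1)
      total <- total + term
      if (term < total * 1e-17) break
    }
    return(structure(log(total), method = "series"))
  }
  # log-space quadrature fallback for large positive s
  lint <- log_beta_exp_shifted(a, b - a, s)
  structure(s + lint - lbeta(a, b - a), method = "quadrature")
}

# log of \int_0^1 x^{a-1} (1-x)^{c-1} e^{s(x-1)} dx for s >= 0.
# Endpoint singularities (a < 1 or c < 1) removed by the substitutions
# x = t^(1/a) on [0, 1/2] and 1 - x = t^(1/c) on [1/2, 1].
log_beta_exp_shifted <- function(a, c, s) {
  left <- stats::integrate(function(t) {
    x <- t^(1 / a)
    (1 / a) * (1 - x)^(c - 1) * exp(s * (x - 1))
  }, 0, 0.5^a, rel.tol = 1e-10, abs.tol = 0)$value
  right <- stats::integrate(function(t) {
    x <- 1 - t^(1 / c)
    (1 / c) * x^(a - 1) * exp(s * (x - 1))
  }, 0, 0.5^c, rel.tol = 1e-10, abs.tol = 0)$value
  log(left + right)
}

#' Stationary density of the population GC frequency at a site
#'
#' Wright's stationary distribution for a biallelic site under reversible
#' mutation and genic selection: phi(x) proportional to
#' `exp(S x) x^(V-1) (1-x)^(U-1)`, normalized in closed form by
#' `Beta(V, U) 1F1(V; U+V; S)`.
#'
#' @param x Frequency (vector) in (0, 1).
#' @param p A [theory_params()] (constant-rate model).
#' @return Density values at `x`.
#' @export
stationary_density <- function(x, p) {
  stopifnot(inherits(p, "theory_params"))
  if (any(x <= 0 | x >= 1)) stop("x must lie strictly in (0, 1)")
  lnorm <- lbeta(p$V, p$U) + as.numeric(log1F1(p$V, p$U + p$V, p$S))
  exp(p$S * x + (p$V - 1) * log(x) + (p$U - 1) * log1p(-x) - lnorm)
}

# constant-rate sampling pmf on a log-safe path; returns probability vector
sample_pmf_constant <- function(U, V, S, n) {
  i <- 0:n
  lnum <- lchoose(n, i) + lbeta(V + i, U + n - i) +
    vapply(i, function(ii) as.numeric(log1F1(V + ii, U + V + n, S)), numeric(1))
  lden <- lbeta(V, U) + as.numeric(log1F1(V, U + V, S))
  probs <- exp(lnum - lden)
  # the U = V, S = 0 model is exactly symmetric; enforce it bitwise so that
  # downstream tail sums cannot pick up last-ulp asymmetries
  if (U == V && S == 0) probs <- (probs + rev(probs)) / 2
  probs
}

#' Probability of observing i GC alleles in a sample of n
#'
#' Integrates binomial sampling over the stationary density: in closed form
#' `P(i) = C(n,i) Beta(V+i, U+n-i) 1F1(V+i; U+V+n; S) /
#' [Beta(V,U) 1F1(V; U+V; S)]`. Under the exponential rate model the pmf is
#' averaged over per-site rates `r * theta`, `r ~ Exponential(mean 1)`, by
#' Gauss-Laguerre quadrature (64 nodes).
#'
#' @param p A [theory_params()].
#' @return An object of class `sample_spectrum`: list with `n`, `probs`
#'   (vector of P(0)..P(n)), `params`, and `method` ("series" or
#'   "quadrature" for the 1F1 evaluation path).
#' @export
sample_pmf <- function(p) {
  stopifnot(inherits(p, "theory_params"))
  n <- p$n
  if (p$rate_model == "constant") {
    probs <- sample_pmf_constant(p$U, p$V, p$S, n)
  } else {
    gl <- gauss_laguerre_64()
    acc <- numeric(n + 1)
    for (k in seq_along(gl$x)) {
      r <- gl$x[k]
      acc <- acc + gl$w[k] *
        sample_pmf_constant(p$U * r, p$V * r, p$S, n)
    }
    probs <- acc / sum(gl$w)   # weights sum to 1 (integral of e^-r)
  }
  tot <- sum(probs)
  # the closed form sums to 1 analytically; drift beyond series/quadrature
  # truncation noise indicates a numerical problem
  if (abs(tot - 1) > 5e-7)
    warning(sprintf("sample_pmf normalization off by %.3g", tot - 1))
  structure(list(n = n, probs = probs / tot, params = p,
                 method = if (abs(p$S) > 50) "quadrature" else "series"),
            class = "sample_spectrum")
}

.gl_cache <- new.env(parent = emptyenv())
gauss_laguerre_64 <- function() {
  if (is.null(.gl_cache$gl)) .gl_cache$gl <- pracma::gaussLaguerre(64)
  .gl_cache$gl
}

# index ranges used for the direction sums: "GC major" classes count toward
# inferred GC->AT, "GC minor" toward AT->GC; the exact tie i = n/2 (even n)
# is excluded, as are the monomorphic classes i = 0 and i = n
z_pred_ranges <- function(n) {
  hi <- seq.int(floor(n / 2) + 1L, n - 1L)
  lo <- seq.int(1L, ceiling(n / 2) - 1L)
  if (n %% 2 == 0) hi <- setdiff(hi, n %/% 2L)
  list(hi = hi, lo = lo)
}

#' Predicted proportion of GC->AT SNPs under the stationary model
#'
#' Applies the minor-allele direction rule to the sampling spectrum: classes
#' with GC in the majority are inferred GC->AT (`U_pred`), classes with GC
#' in the minority AT->GC (`V_pred`); exact ties are excluded. Returns
#' `U_pred / (U_pred + V_pred)`.
#'
#' @param p A [theory_params()].
#' @return Predicted Z in (0, 1).
#' @export
z_pred <- function(p) {
  spec <- sample_pmf(p)
  r <- z_pred_ranges(p$n)
  # summing in sorted order makes the two tails bit-identical under the
  # f = 0.5, S = 0 symmetry, so the neutral prediction is exactly 0.5
  u <- sum(sort(spec$probs[r$hi + 1L]))
  v <- sum(sort(spec$probs[r$lo + 1L]))
  if (u + v <= 0 || !is.finite(u + v))
    stop("degenerate spectrum: no polymorphic probability mass (theta too small?)")
  u / (u + v)
}

#' Expected GC<->AT nucleotide diversity in a sample of n
#'
#' `pi = sum_i P(i) 2 i (n - i) / (n (n - 1))`, the sample-based expected
#' per-site heterozygosity, matching how diversity is measured on data.
#'
#' @param p A [theory_params()].
#' @return Expected diversity (in \[0, 0.5\]).
#' @export
expected_diversity <- function(p) {
  spec <- sample_pmf(p)
  i <- 0:p$n
  sum(spec$probs * 2 * i * (p$n - i) / (p$n * (p$n - 1)))
}

#' Calibrate theta to an observed diversity
#'
#' Finds the scaled mutation rate at which the stationary model reproduces
#' the observed GC<->AT diversity at fourfold sites, by bracketed root
#' finding on log(theta) over \[1e-6, 10\].
#'
#' @param pi_obs Observed diversity, in (0, 0.5).
#' @param f Equilibrium GC fraction (set to the observed GC4 under the
#'   mutation-bias-only null).
#' @param n Sample size.
#' @param S Scaled selection coefficient (0 for the null model).
#' @param rate_model `"constant"` or `"exponential"`.
#' @return Calibrated theta.
#' @export
calibrate_theta <- function(pi_obs, f, n, S = 0,
                            rate_model = c("constant", "exponential")) {
  rate_model <- match.arg(rate_model)
  if (pi_obs <= 0 || pi_obs >= 0.5)
    stop("pi_obs must lie in (0, 0.5)")
  g <- function(lt) {
    expected_diversity(theory_params(exp(lt), f, S, n, rate_model)) - pi_obs
  }
  lo <- log(1e-6); hi <- log(10)
  glo <- g(lo); ghi <- g(hi)
  if (glo > 0 || ghi < 0)
    stop(sprintf(paste0("calibration failure: pi_obs = %g outside attainable",
                        " range [%g, %g] for f = %g, n = %d (%s rates)"),
                 pi_obs, glo + pi_obs, ghi + pi_obs, f, n, rate_model))
  root <- stats::uniroot(g, c(lo, hi), tol = 1e-10)
  exp(root$root)
}

#' Predicted Z for a species from its observed diversity and GC4
#'
#' Composes [calibrate_theta()] (S = 0, f = observed GC4) with [z_pred()].
#' When a species has genes with different strain counts, pass the vector of
#' per-gene `n`; the median of the per-gene predictions is returned.
#'
#' @param pi_obs Observed GC<->AT diversity at fourfold sites.
#' @param gc4 Observed GC4, used as the equilibrium f under the null.
#' @param n Sample size, or vector of per-gene sample sizes.
#' @param rate_model `"constant"` or `"exponential"`.
#' @return Predicted Z.
#' @export
z_pred_for_species <- function(pi_obs, gc4, n,
                               rate_model = c("constant", "exponential")) {
  rate_model <- match.arg(rate_model)
  zs <- vapply(unique(n), function(nn) {
    th <- calibrate_theta(pi_obs, gc4, nn, S = 0, rate_model = rate_model)
    z_pred(theory_params(th, gc4, 0, nn, rate_model))
  }, numeric(1))
  # median over genes, weighted by how many genes share each n
  stats::median(rep(zs, times = tabulate(match(n, unique(n)))))
}

#' Spread of an exponential rate distribution between two quantiles
#'
#' Ratio of exponential quantiles `ln(1/(1-p_hi)) / ln(1/(1-p_lo))`; the
#' mean cancels, so the ratio characterizes the distribution shape alone.
#'
#' @param p_hi,p_lo Probabilities with `0 < p_lo < p_hi < 1`.
#' @return The quantile ratio.
#' @export
exponential_quantile_ratio <- function(p_hi, p_lo) {
  stopifnot(p_lo > 0, p_hi < 1, p_lo <= p_hi)
  log1p(-p_hi) / log1p(-p_lo)
}

#' Equilibrium GC4 implied by the observed SNP direction counts
#'
#' Under mutation pressure alone, the per-GC-site loss rate is proportional
#' to `U / gc4` and the per-AT-site gain rate to `V / (1 - gc4)`; the
#' content to which the sequence would evolve is the stationary point of
#' this two-state flux balance.
#'
#' @param gc4 Current GC4 in (0, 1).
#' @param U,V Counts of GC->AT and AT->GC SNPs; `U + V > 0`.
#' @return Predicted equilibrium GC4.
#' @export
gc4_pred <- function(gc4, U, V) {
  if (gc4 <= 0 || gc4 >= 1) stop("gc4 must lie strictly in (0, 1)")
  if (U + V <= 0) stop("gc4_pred undefined for U = V = 0")
  loss <- U / gc4
  gain <- V / (1 - gc4)
  gain / (loss + gain)
}

#' Z_pred as a function of selection strength
#'
#' Evaluates [z_pred()] across a grid of scaled selection coefficients at
#' fixed mutation parameters; the curve is non-decreasing in S.
#'
#' @param S_grid Numeric vector of scaled selection coefficients.
#' @param f Equilibrium GC fraction.
#' @param theta Scaled mutation rate.
#' @param n Sample size.
#' @param rate_model Rate model passed through.
#' @return A data frame with columns `S` and `z_pred`.
#' @export
selection_curve <- function(S_grid, f, theta = 0.1, n = 10,
                            rate_model = "constant") {
  z <- vapply(S_grid, function(s)
    z_pred(theory_params(theta, f, s, n, rate_model)), numeric(1))
  data.frame(S = S_grid, z_pred = z)
}

#' Rate of ancestral/derived misinference by the minor-allele rule
#'
#' Simulates a haploid Wright-Fisher population forward in time with
#' reversible GC<->AT mutation at matched scaled rates, tracking the
#' mutation origin at every site: while a site segregates, its ancestral
#' allele is the allele the population was last monomorphic for. At
#' sampling, the minor allele is called derived; the misinference rate is
#' the fraction of non-tie segregating sites at which the minor allele is in
#' fact ancestral. The rate rises with theta (infinite-sites violations) and
#' with asymmetric f.
#'
#' @param p A [theory_params()] with S = 0 (neutral; selection in the origin
#'   tracking is not supported).
#' @param N Population size of the forward simulation (scaled rates are
#'   matched, so N only controls discretization).
#' @param n_sites Number of independent sites simulated in parallel.
#' @param burnin_N Burn-in length in units of N generations.
#' @param epochs Number of sampling epochs after burn-in.
#' @param interval Generations between epochs; the default of N generations
#'   keeps successive epochs approximately decorrelated (shorter intervals
#'   resample the same polymorphisms, shrinking the effective sample and
#'   making `se` optimistic).
#' @param seed Integer seed (mandatory; the simulation is stochastic).
#' @return List with `rate`, `se` (binomial Monte-Carlo standard error),
#'   `n_segregating`, and `flagged` (TRUE when too few segregating sites
#'   were seen, or n = 2 where every polymorphic site is a tie).
#' @export
misinference_rate <- function(p, N = 1000, n_sites = 4000, burnin_N = 10,
                              epochs = 60, interval = N, seed = 1) {
  stopifnot(inherits(p, "theory_params"))
  if (p$S != 0) stop("misinference_rate supports the neutral model (S = 0) only")
  n <- p$n
  if (n == 2) {
    warning("n = 2: every polymorphic site is a tie; rate is 0 over an empty set")
    return(list(rate = 0, se = NA_real_, n_segregating = 0L, flagged = TRUE))
  }
  set.seed(seed)
  u <- p$U / (2 * N)   # per-generation per-copy GC->AT rate
  v <- p$V / (2 * N)
  x <- ifelse(stats::runif(n_sites) < p$f, N, 0L)  # start monomorphic
  anc <- ifelse(x == N, 1L, 0L)                    # 1 = GC ancestral
  step <- function(x) {
    pr <- x / N
    pr <- pr * (1 - u) + (1 - pr) * v
    stats::rbinom(n_sites, N, pr)
  }
  for (g in seq_len(burnin_N * N)) {
    x <- step(x)
    anc[x == 0L] <- 0L
    anc[x == N]  <- 1L
  }
  mis <- 0L; seg <- 0L
  for (e in seq_len(epochs)) {
    for (g in seq_len(interval)) {
      x <- step(x)
      anc[x == 0L] <- 0L
      anc[x == N]  <- 1L
    }
    i <- stats::rhyper(n_sites, x, N - x, n)
    poly <- i > 0L & i < n & (2L * i != n)
    if (!any(poly)) next
    minor_gc <- i[poly] < (n - i[poly])
    mis <- mis + sum(ifelse(minor_gc, anc[poly] == 1L, anc[poly] == 0L))
    seg <- seg + sum(poly)
  }
  flagged <- seg < 200L
  if (flagged) warning("fewer than 200 segregating sites; rate is imprecise")
  rate <- if (seg > 0) mis / seg else 0
  list(rate = rate,
       se = if (seg > 0) sqrt(rate * (1 - rate) / seg) else NA_real_,
       n_segregating = as.integer(seg), flagged = flagged)
}
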