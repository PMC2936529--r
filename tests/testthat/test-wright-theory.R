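test_that("stationary density is a normalized, symmetric-when-neutral density", {
  p <- theory_params(0.1, 0.5, 0, 10)
  x <- seq(0.05, 0.95, by = 0.05)
  expect_equal(stationary_density(x, p), stationary_density(1 - x, p))
  # S = 0 reduces to Beta(V, U)
  p2 <- theory_params(0.2, 0.3, 0, 10)
  expect_equal(stationary_density(x, p2), dbeta(x, p2$V, p2$U), tolerance = 1e-12)
  # normalizer agrees with adaptive quadrature of the kernel (S = 2)
  p3 <- theory_params(0.1, 0.5, 2, 10)
  kern_int <- integrate(function(t) {  # substitution t = x^V on the left
    x <- t^(1 / p3$V)
    (1 / p3$V) * (1 - x)^(p3$U - 1) * exp(2 * x)
  }, 0, 0.5^p3$V, rel.tol = 1e-12)$value +
    integrate(function(t) {
      x <- 1 - t^(1 / p3$U)
      (1 / p3$U) * x^(p3$V - 1) * exp(2 * x)
    }, 0, 0.5^p3$U, rel.tol = 1e-12)$value
  xs <- 0.37
  dens <- exp(2 * xs) * xs^(p3$V - 1) * (1 - xs)^(p3$U - 1) / kern_int
  expect_equal(stationary_density(xs, p3), dens, tolerance = 1e-8)
  expect_error(theory_params(0.1, 1.2, 0, 10), "parameter error")
  expect_error(theory_params(-1, 0.5, 0, 10), "parameter error")
  expect_error(stationary_density(1.5, p), "in \\(0, 1\\)")
})

test_that("sampling pmf matches the quadrature oracle on a parameter grid", {
  for (theta in c(0.01, 0.05, 0.2)) for (f in c(0.3, 0.5, 0.9))
    for (S in c(0, 2)) {
      p <- theory_params(theta, f, S, 10)
      got <- sample_pmf(p)$probs
      want <- quad_pmf_oracle(theta, f, S, 10)
      expect_lt(max(abs(got - want)), 1e-6)
    }
})

test_that("sampling pmf reduces to beta-binomial when neutral and obeys symmetry", {
  p <- theory_params(0.06, 0.8, 0, 12)
  i <- 0:12
  bb <- choose(12, i) * beta(p$V + i, p$U + 12 - i) / beta(p$V, p$U)
  expect_equal(sample_pmf(p)$probs, bb, tolerance = 1e-12)
  # P(i | f, S) = P(n - i | 1 - f, -S)
  a <- sample_pmf(theory_params(0.05, 0.75, 1.3, 9))$probs
  b <- rev(sample_pmf(theory_params(0.05, 0.25, -1.3, 9))$probs)
  expect_equal(a, b, tolerance = 1e-12)
  expect_equal(sum(a), 1, tolerance = 1e-8)
  # large-S fallback path stays finite and ordered
  z_hi <- z_pred(theory_params(0.1, 0.5, 80, 10))
  expect_true(is.finite(z_hi) && z_hi > 0.99)
})

test_that("sampling pmf matches a forward Wright-Fisher simulation", {
  for (cfg in list(c(0.02, 0.8, 0), c(0.05, 0.5, 2))) {
    p <- theory_params(cfg[1], cfg[2], cfg[3], 10)
    th <- sample_pmf(p)$probs
    wf <- wf_pmf_oracle(cfg[1], cfg[2], cfg[3], 10, N = 200,
                        n_sites = 40000, seed = 8)
    tol <- 3 * pmax(wf$se, 1e-4) + 0.25 / 200  # MC error + O(1/N) discretization
    expect_true(all(abs(th - wf$pmf) < tol))
  }
})

test_that("z_pred is exactly 0.5 under neutral symmetry and increases with S", {
  for (theta in c(0.01, 0.1)) for (n in c(8, 10, 11, 50))
    for (rm in c("constant", "exponential"))
      expect_identical(z_pred(theory_params(theta, 0.5, 0, n, rm)), 0.5)
  # strictly increasing in S
  zs <- selection_curve(c(-2, 0, 1, 3, 6), f = 0.5, theta = 0.1, n = 10)$z_pred
  expect_true(all(diff(zs) > 0))
  # f-ordering at fixed S (top to bottom f = 0.7, 0.5, 0.3)
  z_at_S <- vapply(c(0.7, 0.5, 0.3), function(f)
    z_pred(theory_params(0.1, f, 2, 10)), numeric(1))
  expect_true(all(diff(z_at_S) < 0))
  # AT-biased mutation with weak positive selection can still give Z < 0.5
  expect_lt(z_pred(theory_params(0.1, 0.3, 0.1, 10)), 0.5)
  # quadrature agreement for the documented example
  p <- theory_params(0.05, 0.8, 0, 10)
  q <- quad_pmf_oracle(0.05, 0.8, 0, 10)
  r <- gcsel:::z_pred_ranges(10)
  z_q <- sum(q[r$hi + 1]) / (sum(q[r$hi + 1]) + sum(q[r$lo + 1]))
  expect_equal(z_pred(p), z_q, tolerance = 1e-6)
})

test_that("expected diversity behaves like a diversity", {
  # monotone increasing in theta, to 0 as theta -> 0
  pis <- vapply(c(1e-4, 1e-3, 0.01, 0.1, 1),
                function(t) expected_diversity(theory_params(t, 0.7, 0, 10)),
                numeric(1))
  expect_true(all(diff(pis) > 0))
  expect_lt(pis[1], 1e-3)
  # symmetric in f when neutral
  expect_equal(expected_diversity(theory_params(0.05, 0.3, 0, 8)),
               expected_diversity(theory_params(0.05, 0.7, 0, 8)),
               tolerance = 1e-12)
  # forward-simulation agreement
  p <- theory_params(0.02, 0.7, 0, 8)
  wf <- wf_pmf_oracle(0.02, 0.7, 0, 8, N = 200, n_sites = 40000, seed = 4)
  i <- 0:8
  pi_wf <- sum(wf$pmf * 2 * i * (8 - i) / (8 * 7))
  expect_lt(abs(expected_diversity(p) - pi_wf), 3 * sqrt(0.5 * pi_wf / 40000) + 2 / 200)
})

test_that("theta calibration inverts expected diversity", {
  for (theta in c(0.005, 0.05, 0.2)) for (f in c(0.3, 0.5, 0.9)) {
    pi_t <- expected_diversity(theory_params(theta, f, 0, 10))
    expect_equal(calibrate_theta(pi_t, f, 10), theta, tolerance = 1e-5)
  }
  # monotonicity over the bracket (scan)
  scan <- vapply(exp(seq(log(1e-6), log(10), length.out = 25)),
                 function(t) expected_diversity(theory_params(t, 0.9, 0, 10)),
                 numeric(1))
  expect_true(all(diff(scan) > 0))
  # exponential rates need a larger theta for the same diversity at high f
  th_c <- calibrate_theta(0.05, 0.9, 10, rate_model = "constant")
  th_e <- calibrate_theta(0.05, 0.9, 10, rate_model = "exponential")
  expect_gte(th_e, th_c)
  expect_error(calibrate_theta(0.49, 0.99, 2), "calibration failure")
})

test_that("species-level predicted Z reproduces the null behaviour", {
  # near 0.5 for moderate GC4 and low diversity
  for (gc4 in c(0.3, 0.5, 0.7))
    expect_lt(abs(z_pred_for_species(0.02, gc4, 10) - 0.5), 0.01)
  # |z_pred - 0.5| < 0.02 whenever diversity < 0.02 and f <= 0.7
  for (gc4 in c(0.6, 0.7)) for (pi in c(0.005, 0.019))
    expect_lt(abs(z_pred_for_species(pi, gc4, 10) - 0.5), 0.02)
  # substantially biased at extreme GC4 and high diversity
  z_ext <- z_pred_for_species(0.08, 0.95, 10)
  expect_gt(z_ext, 0.5)
  # exponential rates make the bias more extreme
  z_c <- z_pred_for_species(0.05, 0.9, 10, "constant")
  z_e <- z_pred_for_species(0.05, 0.9, 10, "exponential")
  expect_gt(z_e, z_c)
  # median-over-genes convention for mixed strain counts
  z_med <- z_pred_for_species(0.05, 0.9, c(8, 10, 12))
  z_each <- vapply(c(8, 10, 12), function(n) z_pred_for_species(0.05, 0.9, n),
                   numeric(1))
  expect_equal(z_med, median(z_each))
})

test_that("exponential quantile ratios match the analytic form", {
  expect_equal(exponential_quantile_ratio(0.95, 0.05),
               log(1 - 0.95) / log(1 - 0.05), tolerance = 1e-12)
  expect_equal(round(exponential_quantile_ratio(0.95, 0.05)), 58)
  expect_equal(round(exponential_quantile_ratio(0.99, 0.01)), 458)
  expect_equal(exponential_quantile_ratio(0.4, 0.4), 1)
})

test_that("predicted equilibrium GC4 follows the flux balance", {
  expect_equal(gc4_pred(0.42, 50, 50), 0.42)   # U = V: stationary point
  expect_equal(gc4_pred(0.6, 80, 0), 0)        # pure GC loss
  expect_equal(gc4_pred(0.7, 100, 50), 0.53846, tolerance = 1e-4)
  # two-state Markov stationary oracle: iterate the per-site chain
  g <- 0.7; U <- 100; V <- 50
  loss <- U / g; gain <- V / (1 - g)
  eps <- 1e-4  # small step so the discrete chain approximates the flux ODE
  P <- matrix(c(1 - loss * eps, loss * eps, gain * eps, 1 - gain * eps),
              2, 2, byrow = TRUE)
  v <- c(0.5, 0.5)
  for (k in 1:200) v <- v %*% (P %*% P %*% P %*% P)
  expect_equal(gc4_pred(g, U, V), v[1], tolerance = 1e-6)
  expect_error(gc4_pred(1, 10, 5), "strictly")
  expect_error(gc4_pred(0.5, 0, 0), "undefined")
})

test_that("misinference rate matches the neutral low-rate spectrum", {
  p <- theory_params(0.01, 0.5, 0, 10)
  mr <- misinference_rate(p, N = 400, n_sites = 6000, burnin_N = 8,
                          epochs = 25, seed = 5)
  closed <- sum(1 / 6:9) / (sum(1 / 1:9) - 1 / 5)
  expect_lt(abs(mr$rate - closed), 3 * mr$se + 0.01)
  expect_gt(mr$n_segregating, 200)
  # n = 2: every polymorphic site is a tie
  expect_warning(r2 <- misinference_rate(theory_params(0.01, 0.5, 0, 2),
                                         N = 100, n_sites = 100, burnin_N = 1,
                                         epochs = 1, seed = 1))
  expect_equal(r2$rate, 0)
  expect_true(r2$flagged)
})

test_that("misinference rate decreases with sample size at low theta", {
  p5 <- theory_params(0.01, 0.5, 0, 5)
  p20 <- theory_params(0.01, 0.5, 0, 20)
  r5 <- misinference_rate(p5, N = 400, n_sites = 6000, burnin_N = 8,
                          epochs = 20, seed = 9)
  r20 <- misinference_rate(p20, N = 400, n_sites = 6000, burnin_N = 8,
                           epochs = 20, seed = 9)
  expect_gt(r5$rate, r20$rate)
})
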