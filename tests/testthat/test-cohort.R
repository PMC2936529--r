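# minimal hand-built per-gene inputs
toy_snps <- function(u4, v4, u2 = 0, v2 = 0, gene = "g1", singleton_u = 0) {
  n <- u4 + v4 + u2 + v2
  if (n == 0) return(gcsel:::empty_snp_table())
  deg <- c(rep("fourfold", u4 + v4), rep("twofold", u2 + v2))
  dir <- c(rep("GC_to_AT", u4), rep("AT_to_GC", v4),
           rep("GC_to_AT", u2), rep("AT_to_GC", v2))
  data.frame(species = "sp", gene = gene, codon_index = seq_len(n),
             degeneracy = deg, allele1 = "C", count1 = 7L, allele2 = "T",
             count2 = 3L, snp_class = "GC_AT", direction_freq = dir,
             direction_parsimony = "not_evaluated",
             singleton = seq_len(n) <= singleton_u, stringsAsFactors = FALSE)
}
toy_div <- function(pi = 0.02, gc4 = 0.6, n4 = 1000, n2 = 400, n = 10)
  list(pi_gc_at_4fold = pi, n_4fold_sites = n4, n_2fold_sites = n2,
       gc4 = gc4, gc2 = gc4, n_strains = n)

test_that("species summaries pool counts and apply the stated filters", {
  s <- summarize_species(list(toy_snps(7, 3)), list(toy_div()),
                         species = "sp", zpred_models = character(0))
  expect_equal(s$Z, 0.7)
  expect_equal(c(s$U4, s$V4), c(7L, 3L))
  expect_true(s$passes_filters)   # 10 strains, 10 SNPs, pi = 0.02

  # boundary fixtures: exactly 10 SNPs included, pi = 0.1 excluded, 7 strains excluded
  s10 <- summarize_species(list(toy_snps(5, 5)), list(toy_div()),
                           species = "sp", zpred_models = character(0))
  expect_true(s10$passes_filters)
  s9 <- summarize_species(list(toy_snps(5, 4)), list(toy_div()),
                          species = "sp", zpred_models = character(0))
  expect_false(s9$passes_filters)
  spi <- summarize_species(list(toy_snps(7, 5)), list(toy_div(pi = 0.1)),
                           species = "sp", zpred_models = character(0))
  expect_false(spi$passes_filters)
  sn <- summarize_species(list(toy_snps(7, 5)), list(toy_div(n = 7)),
                          species = "sp", zpred_models = character(0))
  expect_false(sn$passes_filters)
  s8 <- summarize_species(list(toy_snps(7, 5)), list(toy_div(n = 8)),
                          species = "sp", zpred_models = character(0))
  expect_true(s8$passes_filters)

  # pooling across genes is order-invariant and site-weighted
  g1 <- toy_snps(4, 1, gene = "g1"); g2 <- toy_snps(3, 6, gene = "g2")
  d1 <- toy_div(pi = 0.01, gc4 = 0.5, n4 = 500)
  d2 <- toy_div(pi = 0.03, gc4 = 0.8, n4 = 1500)
  a <- summarize_species(list(g1, g2), list(d1, d2), species = "sp",
                         zpred_models = character(0))
  b <- summarize_species(list(g2, g1), list(d2, d1), species = "sp",
                         zpred_models = character(0))
  expect_equal(c(a$U4, a$V4), c(7L, 7L))
  expect_equal(a$GC4, (0.5 * 500 + 0.8 * 1500) / 2000)
  expect_equal(a[, -1], b[, -1])

  # singleton handling
  gs <- toy_snps(6, 4, singleton_u = 2)
  only <- summarize_species(list(gs), list(toy_div()), species = "sp",
                            singletons_only = TRUE, zpred_models = character(0))
  expect_equal(c(only$U4, only$V4), c(2L, 0L))
  drop <- summarize_species(list(gs), list(toy_div()), species = "sp",
                            drop_singletons = TRUE, zpred_models = character(0))
  expect_equal(c(drop$U4, drop$V4), c(4L, 4L))

  # gene allowlist keeps only named genes
  al <- summarize_species(list(g1, g2), list(d1, d2), species = "sp",
                          gene_allowlist = "g1", zpred_models = character(0))
  expect_equal(c(al$U4, al$V4), c(4L, 1L))
  expect_error(summarize_species(list(g1), list(d1), gene_allowlist = "zz",
                                 zpred_models = character(0)),
               "empty summary")
})

test_that("exact two-tail binomial test matches enumeration and binom.test", {
  expect_equal(binomial_two_tail(5, 5), 1)
  expect_equal(binomial_two_tail(7, 3), 0.34375)  # 2 * P(X <= 3), X ~ B(10, .5)
  expect_equal(binomial_two_tail(7, 3),
               binom.test(7, 10, 0.5)$p.value, tolerance = 1e-12)
  expect_lt(binomial_two_tail(11045, 8309), 1e-4)
  expect_equal(binomial_two_tail(12, 0), 2 * 0.5^12)
})

test_that("Z-on-GC4 regression finds the crossing with a reproducible bootstrap", {
  d <- data.frame(species = c("a", "b", "c"), GC4 = c(0.2, 0.5, 0.8),
                  Z = c(0.4, 0.5, 0.6))
  r <- fit_z_regression(d, n_boot = 100, seed = 2)
  expect_equal(r$crossing_gc4, 0.5, tolerance = 1e-12)
  expect_equal(r$r, 1, tolerance = 1e-12)

  flat <- data.frame(species = letters[1:4], GC4 = c(0.2, 0.4, 0.6, 0.8),
                     Z = rep(0.55, 4))
  expect_error(fit_z_regression(flat, n_boot = 10, seed = 1),
               "slope is zero")

  set.seed(99)
  d2 <- data.frame(species = sprintf("s%02d", 1:30),
                   GC4 = runif(30, 0.1, 0.9))
  d2$Z <- 0.25 + 0.5 * d2$GC4 + rnorm(30, 0, 0.05)
  r1 <- fit_z_regression(d2, n_boot = 500, seed = 11)
  r2 <- fit_z_regression(d2, n_boot = 500, seed = 11)
  expect_identical(c(r1$ci_low, r1$ci_high), c(r2$ci_low, r2$ci_high))
  expect_true(r1$ci_low <= r1$crossing_gc4 && r1$crossing_gc4 <= r1$ci_high)

  # endpoints stabilize as the number of resamples grows: seed-to-seed
  # spread of the lower endpoint shrinks
  spread <- function(nb) {
    los <- vapply(1:6, function(s)
      fit_z_regression(d2, n_boot = nb, seed = s)$ci_low, numeric(1))
    diff(range(los))
  }
  expect_lt(spread(2000), spread(50))
})

test_that("sign tests count predicates over GC-rich and AT-rich subsets", {
  d <- data.frame(species = letters[1:6], GC4 = c(0.7, 0.8, 0.9, 0.2, 0.25, 0.3),
                  Z = c(0.6, 0.7, 0.45, 0.4, 0.55, 0.35),
                  Z_pred_constant = rep(0.5, 6),
                  Z_pred_exponential = rep(0.5, 6),
                  GC4_pred = c(0.5, 0.6, 0.95, 0.1, 0.2, 0.4))
  d <- classify_gc_rich(d, threshold = 0.5)
  gc <- sign_counts(d, "z_gt_half", "gc_rich")
  expect_equal(c(gc$k, gc$m), c(2L, 3L))
  at <- sign_counts(d, "z_lt_half", "at_rich")
  expect_equal(c(at$k, at$m), c(2L, 3L))
  # all species satisfying the predicate: exact extreme two-tail p
  all_d <- data.frame(species = letters[1:5], GC4 = seq(0.6, 0.9, length.out = 5),
                      Z = rep(0.8, 5), Z_pred_constant = 0.5,
                      Z_pred_exponential = 0.5, GC4_pred = 0.4)
  all_d <- classify_gc_rich(all_d, threshold = 0.5)
  ex <- sign_counts(all_d, "z_gt_half", "gc_rich")
  expect_equal(ex$p_value, 2 * 0.5^5)
  expect_error(sign_counts(all_d, "z_gt_half", "at_rich"), "empty subset")
})

test_that("translational contrast compares pooled GC4 between gene sets", {
  hi <- make_aln(rep(strrep("GGG", 10), 4))   # all fourfold, third = G
  lo <- make_aln(rep(strrep("GGA", 10), 4))   # all fourfold, third = A
  tc <- translational_contrast(list(hi), list(lo))
  expect_equal(c(tc$gc4_high, tc$gc4_other), c(1, 0))
  expect_equal(tc$sign, 1)
  same <- translational_contrast(list(hi), list(hi))
  expect_equal(same$sign, 0)
  expect_error(translational_contrast(list(), list(hi)), "empty gene set")
})

test_that("r/m correlations handle planted, null and degenerate inputs", {
  set.seed(3)
  d <- data.frame(species = sprintf("s%02d", 1:20),
                  GC4 = runif(20, 0.2, 0.8), Z = runif(20, 0.3, 0.7),
                  Z_pred_constant = 0.5, Z_pred_exponential = 0.5,
                  pi_gc_at_4fold = runif(20, 0.01, 0.08))
  # perfect linear dependence on GC4
  rm_lin <- data.frame(species = d$species, rm = 2 + 3 * d$GC4)
  rc <- recombination_correlations(d, rm_lin)
  expect_equal(rc$r[rc$statistic == "rm" & rc$variable == "GC4"], 1,
               tolerance = 1e-10)
  # independent r/m: small correlation with Z (fixed seed)
  rm_null <- data.frame(species = d$species, rm = runif(20, 1, 10))
  rn <- recombination_correlations(d, rm_null)
  expect_lt(abs(rn$r[rn$statistic == "rm" & rn$variable == "Z"]), 0.6)
  # zero-variance r/m flagged as NA with a note
  rm_const <- data.frame(species = d$species, rm = 2)
  rz <- recombination_correlations(d, rm_const)
  expect_true(all(is.na(rz$r[rz$statistic == "rm"])))
  expect_match(rz$note[1], "zero variance")
  expect_error(recombination_correlations(d[1:2, ], rm_lin), "fewer than 3")
})
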