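#' Pool per-gene SNP tables into a species summary
#'
#' Pools GC->AT (`U`) and AT->GC (`V`) counts across genes at fourfold and
#' twofold sites, using the chosen direction method (ties and ambiguous
#' parsimony calls are discarded). GC4, GC2 and the GC<->AT diversity are
#' site-count-weighted across genes. The predicted Z under the
#' mutation-bias-only stationary null is computed by calibrating theta to
#' the pooled diversity (median over per-gene strain counts); the predicted
#' equilibrium GC4 comes from the flux balance [gc4_pred()].
#'
#' @param snp_tables List of per-gene SNP tables from [extract_snps()]
#'   (with parsimony calls filled if `method = "parsimony"`).
#' @param diversities List of per-gene summaries from [diversity_summary()],
#'   parallel to `snp_tables`.
#' @param species Species label; taken from the first table when `NULL`.
#' @param method Direction method: `"frequency"` or `"parsimony"`.
#' @param singletons_only Restrict U/V counting to singleton SNPs.
#' @param drop_singletons Remove singleton SNPs from U/V counting.
#' @param gene_allowlist Optional character vector of gene names (e.g. an
#'   HGT-resistant gene set); genes outside the list are dropped entirely.
#' @param min_strains,min_gc_at_snps4,max_pi Dataset filters: at least 8
#'   strains, at least 10 GC<->AT fourfold SNPs, diversity below 0.1 by
#'   default.
#' @param zpred_models Character vector of rate models for which predicted Z
#'   is computed (`"constant"`, `"exponential"`, both, or none).
#' @param phylum,class_name Optional taxonomy metadata carried through.
#' @return One-row data frame (a species summary) with columns `species`,
#'   `phylum`, `class_name`, `n_genes`, `n_strains_median`, `U4`, `V4`,
#'   `U2`, `V2`, `Z`, `GC4`, `GC2`, `pi_gc_at_4fold`, `GC4_pred`,
#'   `Z_pred_constant`, `Z_pred_exponential`, `passes_filters`, `gc_rich`
#'   (filled later by [classify_gc_rich()]).
#' @export
summarize_species <- function(snp_tables, diversities, species = NULL,
                              method = c("frequency", "parsimony"),
                              singletons_only = FALSE, drop_singletons = FALSE,
                              gene_allowlist = NULL,
                              min_strains = 8, min_gc_at_snps4 = 10,
                              max_pi = 0.1,
                              zpred_models = c("constant", "exponential"),
                              phylum = "", class_name = "") {
  method <- match.arg(method)
  if (singletons_only && drop_singletons)
    stop("singletons_only and drop_singletons are mutually exclusive")
  stopifnot(length(snp_tables) == length(diversities))
  if (!is.null(gene_allowlist)) {
    # genes are mapped to the allowlist by name: list names take precedence,
    # else the gene column of the SNP table
    keep <- vapply(seq_along(snp_tables), function(k) {
      nm <- names(snp_tables)[k]
      if (!is.null(nm) && nzchar(nm)) return(nm %in% gene_allowlist)
      t <- snp_tables[[k]]
      nrow(t) > 0 && t$gene[1] %in% gene_allowlist
    }, logical(1))
    snp_tables <- snp_tables[keep]
    diversities <- diversities[keep]
  }
  if (length(snp_tables) == 0)
    stop("empty summary: no qualifying genes")
  if (is.null(species)) {
    sp <- unlist(lapply(snp_tables, function(t) t$species))
    species <- if (length(sp)) sp[1] else ""
  }
  dir_col <- if (method == "frequency") "direction_freq" else "direction_parsimony"
  count_uv <- function(deg) {
    u <- 0L; v <- 0L
    for (t in snp_tables) {
      if (nrow(t) == 0) next
      rows <- t$snp_class == "GC_AT" & t$degeneracy == deg
      if (singletons_only) rows <- rows & t$singleton
      if (drop_singletons) rows <- rows & !t$singleton
      u <- u + sum(rows & t[[dir_col]] == "GC_to_AT")
      v <- v + sum(rows & t[[dir_col]] == "AT_to_GC")
    }
    c(u, v)
  }
  uv4 <- count_uv("fourfold"); uv2 <- count_uv("twofold")
  w4 <- vapply(diversities, function(d) d$n_4fold_sites, numeric(1))
  w2 <- vapply(diversities, function(d) d$n_2fold_sites, numeric(1))
  gc4 <- stats::weighted.mean(vapply(diversities, `[[`, numeric(1), "gc4"), w4)
  gc2v <- vapply(diversities, `[[`, numeric(1), "gc2")
  gc2 <- if (sum(w2) > 0) stats::weighted.mean(gc2v, w2, na.rm = TRUE) else NA_real_
  pi4 <- stats::weighted.mean(
    vapply(diversities, `[[`, numeric(1), "pi_gc_at_4fold"), w4)
  ns <- vapply(diversities, `[[`, numeric(1), "n_strains")
  n_med <- stats::median(ns)
  zp_c <- zp_e <- NA_real_
  if (pi4 > 0 && gc4 > 0 && gc4 < 1) {
    if ("constant" %in% zpred_models)
      zp_c <- tryCatch(z_pred_for_species(pi4, gc4, ns, "constant"),
                       error = function(e) NA_real_)
    if ("exponential" %in% zpred_models)
      zp_e <- tryCatch(z_pred_for_species(pi4, gc4, ns, "exponential"),
                       error = function(e) NA_real_)
  }
  U4 <- uv4[1]; V4 <- uv4[2]
  data.frame(
    species = species, phylum = phylum, class_name = class_name,
    n_genes = length(snp_tables), n_strains_median = n_med,
    U4 = U4, V4 = V4, U2 = uv2[1], V2 = uv2[2],
    Z = if (U4 + V4 > 0) U4 / (U4 + V4) else NA_real_,
    GC4 = gc4, GC2 = gc2, pi_gc_at_4fold = pi4,
    GC4_pred = if (U4 + V4 > 0 && gc4 > 0 && gc4 < 1)
      gc4_pred(gc4, U4, V4) else NA_real_,
    Z_pred_constant = zp_c, Z_pred_exponential = zp_e,
    passes_filters = (n_med >= min_strains) && (U4 + V4 >= min_gc_at_snps4) &&
      (pi4 < max_pi),
    gc_rich = NA,
    stringsAsFactors = FALSE)
}

#' Exact two-tailed binomial test against 0.5
#'
#' `p = 2 min(P(X <= min(U,V)), P(X >= max(U,V)))` for
#' `X ~ Binomial(U + V, 1/2)`, capped at 1.
#'
#' @param U,V Non-negative counts with `U + V >= 1`.
#' @return The p-value.
#' @export
binomial_two_tail <- function(U, V) {
  m <- U + V
  if (m < 1) stop("U + V must be at least 1")
  lo <- min(U, V); hi <- max(U, V)
  p <- 2 * min(stats::pbinom(lo, m, 0.5),
               stats::pbinom(hi - 1, m, 0.5, lower.tail = FALSE))
  min(p, 1)
}

#' Regression of Z on GC4 with a bootstrap CI for the Z = 0.5 crossing
#'
#' Ordinary least squares of Z on GC4 across species; the GC4 value at which
#' the fitted line crosses Z = 0.5 separates GC-rich from AT-rich species.
#' The crossing's confidence interval is a percentile bootstrap over species
#' resamples.
#'
#' @param summaries Data frame of species summaries (rows from
#'   [summarize_species()]).
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level.
#' @return List with `slope`, `intercept`, `crossing_gc4`, `r` (Pearson),
#'   `p_value`, `ci_low`, `ci_high`, `n_boot`, `seed`, `n_species`,
#'   `point_outside_ci` flag.
#' @export
fit_z_regression <- function(summaries, n_boot = 1000, seed = 1, conf = 0.95) {
  d <- summaries[!is.na(summaries$Z) & !is.na(summaries$GC4), , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 species with defined Z")
  fit <- stats::lm(Z ~ GC4, data = d)
  slope <- unname(stats::coef(fit)[2]); intercept <- unname(stats::coef(fit)[1])
  if (abs(slope) < .Machine$double.eps * 100)
    stop("crossing undefined: regression slope is zero")
  crossing <- (0.5 - intercept) / slope
  ct <- stats::cor.test(d$GC4, d$Z)
  set.seed(seed)
  boots <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(d), replace = TRUE)
    db <- d[idx, ]
    if (stats::var(db$GC4) == 0) next
    cf <- stats::coef(stats::lm(Z ~ GC4, data = db))
    if (abs(cf[2]) > 0) boots[b] <- (0.5 - cf[1]) / cf[2]
  }
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  list(slope = slope, intercept = intercept, crossing_gc4 = crossing,
       r = unname(ct$estimate), p_value = ct$p.value,
       ci_low = qs[1], ci_high = qs[2], n_boot = n_boot, seed = seed,
       n_species = nrow(d),
       point_outside_ci = crossing < qs[1] || crossing > qs[2])
}

#' Flag species as GC-rich relative to a threshold
#'
#' @param summaries Species summary data frame.
#' @param threshold `"auto"` (re-fit the crossing via [fit_z_regression()])
#'   or a fixed GC4 value (e.g. 0.34 to reproduce a fixed classification).
#' @param ... Passed to [fit_z_regression()] when `threshold = "auto"`.
#' @return The summaries with `gc_rich` filled (GC4 > threshold).
#' @export
classify_gc_rich <- function(summaries, threshold = "auto", ...) {
  thr <- if (identical(threshold, "auto"))
    fit_z_regression(summaries, ...)$crossing_gc4 else threshold
  summaries$gc_rich <- summaries$GC4 > thr
  attr(summaries, "gc_rich_threshold") <- thr
  summaries
}

#' Sign test over a species subset
#'
#' Counts species satisfying a predicate among a subset (GC-rich, AT-rich
#' or all) and tests the count against a fair coin with the exact two-tail
#' binomial test.
#'
#' @param summaries Species summaries with `gc_rich` filled.
#' @param predicate One of `"z_gt_half"`, `"z_lt_half"`,
#'   `"z_gt_zpred_constant"`, `"z_lt_zpred_constant"`,
#'   `"z_gt_zpred_exponential"`, `"z_lt_zpred_exponential"`,
#'   `"gc4pred_lt_gc4"`.
#' @param subset `"gc_rich"`, `"at_rich"` or `"all"`.
#' @return List with `k` (satisfying), `m` (subset size), `fraction`,
#'   `p_value`.
#' @export
sign_counts <- function(summaries,
                        predicate = c("z_gt_half", "z_lt_half",
                                      "z_gt_zpred_constant", "z_lt_zpred_constant",
                                      "z_gt_zpred_exponential", "z_lt_zpred_exponential",
                                      "gc4pred_lt_gc4"),
                        subset = c("gc_rich", "at_rich", "all")) {
  predicate <- match.arg(predicate)
  subset <- match.arg(subset)
  d <- switch(subset,
              gc_rich = summaries[isTRUE_vec(summaries$gc_rich), , drop = FALSE],
              at_rich = summaries[!isTRUE_vec(summaries$gc_rich), , drop = FALSE],
              all = summaries)
  val <- switch(predicate,
                z_gt_half = d$Z > 0.5,
                z_lt_half = d$Z < 0.5,
                z_gt_zpred_constant = d$Z > d$Z_pred_constant,
                z_lt_zpred_constant = d$Z < d$Z_pred_constant,
                z_gt_zpred_exponential = d$Z > d$Z_pred_exponential,
                z_lt_zpred_exponential = d$Z < d$Z_pred_exponential,
                gc4pred_lt_gc4 = d$GC4_pred < d$GC4)
  val <- val[!is.na(val)]
  m <- length(val)
  if (m == 0) stop("empty subset for sign test")
  k <- sum(val)
  list(k = k, m = m, fraction = k / m, p_value = binomial_two_tail(k, m - k))
}

isTRUE_vec <- function(x) !is.na(x) & x

#' GC4 contrast between highly expressed and other genes
#'
#' Compares pooled (site-weighted) GC4 of a set of putatively highly
#' expressed genes (ribosomal proteins, elongation factors) against the
#' rest; translational selection favouring AT-rich optimal codons shows up
#' as `GC4_high < GC4_other`.
#'
#' @param high_alns,other_alns Lists of [codon_alignment()] objects.
#' @param code Genetic code id.
#' @return List with `gc4_high`, `gc4_other`, `sign` (-1, 0, 1 for
#'   high < other, equal, high > other).
#' @export
translational_contrast <- function(high_alns, other_alns, code = 11) {
  pooled_gc4 <- function(alns) {
    if (length(alns) == 0) stop("empty gene set")
    tot_gc <- 0; tot_n <- 0
    for (a in alns) {
      sites <- classify_sites(a, code)
      i4 <- which(sites$degeneracy == "fourfold")
      if (length(i4) == 0) next
      third <- a$bases[, 3L * i4, drop = FALSE]
      tot_gc <- tot_gc + sum(third %in% c("C", "G"))
      tot_n <- tot_n + length(third)
    }
    if (tot_n == 0) stop("no valid fourfold sites in gene set")
    tot_gc / tot_n
  }
  hi <- pooled_gc4(high_alns); ot <- pooled_gc4(other_alns)
  list(gc4_high = hi, gc4_other = ot, sign = sign(hi - ot))
}

#' Correlations between recombination rate and GC/Z statistics
#'
#' Joins a per-species r/m table (relative impact of recombination vs
#' mutation) onto the summaries and reports Pearson correlations (two-sided
#' p via the t transform) of r/m — and of r/m multiplied by the GC<->AT
#' fourfold diversity, a proxy for the population-scaled recombination rate
#' 2 N_e q — against GC4, Z, and Z - Z_pred under both rate models.
#'
#' @param summaries Species summaries.
#' @param rm_table Data frame with columns `species` and `rm`.
#' @return Data frame with columns `statistic`, `variable`, `r`, `p`, `n`;
#'   `r` is `NA` with a note when a variable has zero variance.
#' @export
recombination_correlations <- function(summaries, rm_table) {
  d <- merge(summaries, rm_table, by = "species")
  if (nrow(d) < 3) stop("fewer than 3 species match the r/m table")
  d$rm_pi <- d$rm * d$pi_gc_at_4fold
  vars <- list(GC4 = d$GC4, Z = d$Z,
               Z_minus_Zpred_constant = d$Z - d$Z_pred_constant,
               Z_minus_Zpred_exponential = d$Z - d$Z_pred_exponential)
  rows <- list()
  for (stat_name in c("rm", "rm_pi")) {
    x <- d[[stat_name]]
    for (vn in names(vars)) {
      y <- vars[[vn]]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3 || stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          statistic = stat_name, variable = vn, r = NA_real_, p = NA_real_,
          n = sum(ok), note = "zero variance or too few species")
        next
      }
      ct <- stats::cor.test(x[ok], y[ok])
      rows[[length(rows) + 1]] <- data.frame(
        statistic = stat_name, variable = vn, r = unname(ct$estimate),
        p = ct$p.value, n = sum(ok), note = "")
    }
  }
  do.call(rbind, rows)
}

#' Write a species summary table as TSV
#'
#' @param summaries Species summary data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_species_summary <- function(summaries, path) {
  utils::write.table(summaries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
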