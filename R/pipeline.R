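#' Run the full polymorphism-direction analysis on a directory of alignments
#'
#' Input layout: `input_dir/<species>/<gene>.fasta`, each file an in-frame
#' aligned FASTA of conspecific strains. For every gene the pipeline
#' classifies sites, extracts SNPs, infers directions (frequency always;
#' parsimony when requested), runs the recombination screens, and summarizes
#' per species. Species-level filters (strain count, SNP count, diversity)
#' are applied, the Z-vs-GC4 regression with its bootstrap crossing CI is
#' fitted, sign tests are run, and screen-filtered re-analyses are produced
#' side by side with the unfiltered one (screens exclude datasets, they do
#' not mutate the primary summary).
#'
#' @param input_dir Directory of species subdirectories with gene FASTAs.
#' @param method Direction method for the pooled counts: `"frequency"`
#'   (default) or `"parsimony"`.
#' @param rate_model `"constant"`, `"exponential"`, or `"both"` for the
#'   predicted-Z models.
#' @param filters List with `min_strains` (8), `min_gc_at_snps4` (10),
#'   `max_pi` (0.1) — the default dataset filters.
#' @param screens List with `fgt`, `maxchi` (logical switches) and
#'   `maxchi_perms`.
#' @param singletons_only,drop_singletons,gene_allowlist Passed to
#'   [summarize_species()].
#' @param rm_table Optional data frame (`species`, `rm`) of per-species
#'   recombination-to-mutation ratios for [recombination_correlations()].
#' @param gc_rich_threshold `"auto"` (use the fitted crossing) or a fixed
#'   GC4 value.
#' @param n_boot Bootstrap resamples for the regression CI.
#' @param seed Integer seed for every stochastic step.
#' @param code Genetic code id.
#' @return List of class `gcsel_report`: `summaries` (species summary data
#'   frame), `regression`, `sign_tests`, `pooled` (U4/V4/U2/V2 with binomial
#'   p), `screen` (per-dataset screen results and screen-filtered
#'   summaries/sign tests), `rm_correlations` (or `NULL`), `attrition`
#'   (per-filter exclusion accounting), `config`.
#' @export
run_pipeline <- function(input_dir,
                         method = c("frequency", "parsimony"),
                         rate_model = c("both", "constant", "exponential"),
                         filters = list(min_strains = 8, min_gc_at_snps4 = 10,
                                        max_pi = 0.1),
                         screens = list(fgt = TRUE, maxchi = TRUE,
                                        maxchi_perms = 1000),
                         singletons_only = FALSE, drop_singletons = FALSE,
                         gene_allowlist = NULL, rm_table = NULL,
                         gc_rich_threshold = "auto", n_boot = 1000,
                         seed = 1, code = 11) {
  method <- match.arg(method)
  rate_model <- match.arg(rate_model)
  zpred_models <- if (rate_model == "both") c("constant", "exponential")
                  else rate_model
  species_dirs <- list.dirs(input_dir, recursive = FALSE)
  if (length(species_dirs) == 0)
    stop("empty cohort: no species directories under ", input_dir)
  per_species <- list()
  screen_rows <- list()
  for (sd in species_dirs) {
    sp <- basename(sd)
    fastas <- list.files(sd, pattern = "\\.(fa|fasta|fna)$", full.names = TRUE)
    if (length(fastas) == 0) next
    snp_tables <- list(); divs <- list(); gene_screens <- list()
    for (fp in fastas) {
      gene <- sub("\\.[^.]+$", "", basename(fp))
      aln <- read_codon_alignment(fp, species = sp, gene = gene)
      sites <- classify_sites(aln, code)
      if (!any(sites$degeneracy == "fourfold")) next
      snps <- extract_snps(aln, sites)
      if (method == "parsimony" && nrow(snps) > 0 &&
          length(aln$strain_ids) >= 3) {
        tree <- tryCatch(build_strain_tree(aln), error = function(e) NULL)
        if (!is.null(tree)) snps <- add_parsimony_directions(aln, snps, tree)
      }
      div <- diversity_summary(aln, sites)
      snp_tables[[gene]] <- snps
      divs[[gene]] <- div
      scr <- list(species = sp, gene = gene,
                  fgt_violation = NA, maxchi_p = NA_real_)
      if (isTRUE(screens$fgt))
        scr$fgt_violation <- four_gamete_test(aln)$fgt_violation
      if (isTRUE(screens$maxchi)) {
        mx <- maxchi_test(aln, n_perm = screens$maxchi_perms, seed = seed)
        scr$maxchi_p <- mx$maxchi_p
      }
      gene_screens[[gene]] <- scr
    }
    if (length(snp_tables) == 0) next
    per_species[[sp]] <- list(snps = snp_tables, divs = divs,
                              screens = gene_screens)
    screen_rows <- c(screen_rows, unname(gene_screens))
  }
  if (length(per_species) == 0)
    stop("empty cohort: no species with usable alignments")

  summarize_all <- function(gene_filter = NULL) {
    rows <- list(); attrition <- list()
    for (sp in names(per_species)) {
      x <- per_species[[sp]]
      keep <- rep(TRUE, length(x$snps))
      if (!is.null(gene_filter))
        keep <- vapply(names(x$snps), function(g) gene_filter(x$screens[[g]]),
                       logical(1))
      if (!any(keep)) {
        attrition[[sp]] <- "all genes screen-excluded"
        next
      }
      s <- tryCatch(
        summarize_species(x$snps[keep], x$divs[keep], species = sp,
                          method = method,
                          singletons_only = singletons_only,
                          drop_singletons = drop_singletons,
                          gene_allowlist = gene_allowlist,
                          min_strains = filters$min_strains,
                          min_gc_at_snps4 = filters$min_gc_at_snps4,
                          max_pi = filters$max_pi,
                          zpred_models = zpred_models),
        error = function(e) NULL)
      if (is.null(s)) { attrition[[sp]] <- "no qualifying genes"; next }
      rows[[sp]] <- s
    }
    list(summary = if (length(rows)) do.call(rbind, rows) else NULL,
         attrition = attrition)
  }

  primary <- summarize_all()
  if (is.null(primary$summary))
    stop("empty cohort: no species left after per-gene processing")
  summ <- primary$summary
  n_total <- nrow(summ)
  # each excluded species is attributed to the first filter it fails, so
  # that n_input = n_passed + sum of per-filter exclusions
  f1 <- summ$n_strains_median < filters$min_strains
  f2 <- !f1 & (summ$U4 + summ$V4 < filters$min_gc_at_snps4)
  f3 <- !f1 & !f2 & (summ$pi_gc_at_4fold >= filters$max_pi)
  fail_strains <- sum(f1); fail_snps <- sum(f2); fail_pi <- sum(f3)
  passed <- summ[summ$passes_filters, , drop = FALSE]
  if (nrow(passed) == 0)
    stop("empty cohort: no species pass the filters (",
         fail_strains, " fail min_strains, ", fail_snps,
         " fail min_gc_at_snps4, ", fail_pi, " fail max_pi)")

  reg <- if (nrow(passed) >= 3)
    tryCatch(fit_z_regression(passed, n_boot = n_boot, seed = seed),
             error = function(e) NULL) else NULL
  thr <- if (identical(gc_rich_threshold, "auto")) {
    if (!is.null(reg)) reg$crossing_gc4 else 0.5
  } else gc_rich_threshold
  passed <- classify_gc_rich(passed, threshold = thr)

  run_sign_tests <- function(d) {
    out <- list()
    if (any(isTRUE_vec(d$gc_rich)))
      out$gc_rich_z_gt_half <- sign_counts(d, "z_gt_half", "gc_rich")
    if (any(!isTRUE_vec(d$gc_rich)))
      out$at_rich_z_lt_half <- sign_counts(d, "z_lt_half", "at_rich")
    if (any(isTRUE_vec(d$gc_rich)) && any(!is.na(d$Z_pred_constant)))
      out$gc_rich_z_gt_zpred_constant <-
        sign_counts(d, "z_gt_zpred_constant", "gc_rich")
    if (any(isTRUE_vec(d$gc_rich)) && any(!is.na(d$Z_pred_exponential)))
      out$gc_rich_z_gt_zpred_exponential <-
        sign_counts(d, "z_gt_zpred_exponential", "gc_rich")
    out
  }
  sign_tests <- run_sign_tests(passed)

  pooled <- list(U4 = sum(passed$U4), V4 = sum(passed$V4),
                 U2 = sum(passed$U2), V2 = sum(passed$V2))
  pooled$p4 <- if (pooled$U4 + pooled$V4 > 0)
    binomial_two_tail(pooled$U4, pooled$V4) else NA_real_
  pooled$p2 <- if (pooled$U2 + pooled$V2 > 0)
    binomial_two_tail(pooled$U2, pooled$V2) else NA_real_

  screen_out <- list(per_gene = screen_rows)
  if (isTRUE(screens$fgt)) {
    fgt_res <- summarize_all(function(s) !isTRUE(s$fgt_violation))
    if (!is.null(fgt_res$summary)) {
      fg <- fgt_res$summary[fgt_res$summary$passes_filters, , drop = FALSE]
      if (nrow(fg) > 0) {
        fg <- classify_gc_rich(fg, threshold = thr)
        screen_out$fgt_filtered <- list(summaries = fg,
                                        sign_tests = run_sign_tests(fg))
      }
    }
  }
  if (isTRUE(screens$maxchi)) {
    mx_res <- summarize_all(function(s)
      is.na(s$maxchi_p) || s$maxchi_p >= 0.05)
    if (!is.null(mx_res$summary)) {
      mg <- mx_res$summary[mx_res$summary$passes_filters, , drop = FALSE]
      if (nrow(mg) > 0) {
        mg <- classify_gc_rich(mg, threshold = thr)
        screen_out$maxchi_filtered <- list(summaries = mg,
                                           sign_tests = run_sign_tests(mg))
      }
    }
  }

  rm_cor <- if (!is.null(rm_table))
    tryCatch(recombination_correlations(passed, rm_table),
             error = function(e) NULL) else NULL

  structure(list(
    summaries = summ, passed = passed, regression = reg,
    gc_rich_threshold = thr, sign_tests = sign_tests, pooled = pooled,
    screen = screen_out, rm_correlations = rm_cor,
    attrition = list(
      n_species_input = n_total,
      n_passed = nrow(passed),
      fail_min_strains = fail_strains,
      fail_min_gc_at_snps4 = fail_snps,
      fail_max_pi = fail_pi,
      species_errors = primary$attrition),
    config = list(method = method, rate_model = rate_model,
                  filters = filters, screens = screens,
                  singletons_only = singletons_only,
                  drop_singletons = drop_singletons,
                  gc_rich_threshold = gc_rich_threshold, n_boot = n_boot,
                  seed = seed, code = code)),
    class = "gcsel_report")
}

#' @export
print.gcsel_report <- function(x, ...) {
  cat("gcsel cohort report\n")
  cat(sprintf("  species: %d input, %d passing filters\n",
              x$attrition$n_species_input, x$attrition$n_passed))
  cat(sprintf("  pooled 4-fold: U=%d V=%d (Z=%.3f, p=%.3g)\n",
              x$pooled$U4, x$pooled$V4,
              x$pooled$U4 / (x$pooled$U4 + x$pooled$V4), x$pooled$p4))
  if (!is.null(x$regression))
    cat(sprintf("  Z~GC4: r=%.3f, crossing=%.3f (95%% CI %.3f-%.3f)\n",
                x$regression$r, x$regression$crossing_gc4,
                x$regression$ci_low, x$regression$ci_high))
  invisible(x)
}

#' Write a cohort report to a directory
#'
#' Writes the species summary TSV, the screen summary TSV and the cohort
#' JSON (regression, sign tests, pooled counts, attrition, config).
#'
#' @param report A `gcsel_report` from [run_pipeline()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_species_summary(report$summaries, file.path(dir, "species_summary.tsv"))
  if (length(report$screen$per_gene)) {
    scr <- do.call(rbind, lapply(report$screen$per_gene, as.data.frame))
    utils::write.table(scr, file.path(dir, "screen_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  keep <- report[c("regression", "gc_rich_threshold", "sign_tests", "pooled",
                   "attrition", "config")]
  jsonlite::write_json(keep, file.path(dir, "cohort_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
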