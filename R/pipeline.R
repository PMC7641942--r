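#' Format a proportion as "k/n (P%)"
#'
#' The percentage is rounded half-away-from-zero to the nearest integer,
#' the convention used throughout the report.
#'
#' @param k Numerator (0 <= k <= n).
#' @param n Denominator (> 0).
#' @return Character vector like `"63/166 (38%)"`.
#' @examples
#' proportion_report(63, 166)
#' @export
proportion_report <- function(k, n) {
  if (any(n == 0)) abort("denominator must be positive")
  if (any(k < 0 | k > n)) abort("need 0 <= k <= n")
  pct <- floor(abs(100 * k / n) + 0.5)  # half away from zero; k/n >= 0 here
  sprintf("%d/%d (%d%%)", as.integer(k), as.integer(n), as.integer(pct))
}

pipeline_groups <- c("monogenic_NDM", "unknown", "T1D_6_24m")
report_groups <- c("monogenic_NDM", "unknown_low_GRS", "unknown_high_GRS",
                   "T1D_6_24m")

#' Run the full analysis pipeline
#'
#' Executes the stages in order: score the referral cohort from the VCF,
#' classify against the threshold (a fixed value, or the configured centile
#' of the reference score distribution), estimate the excess of high-score
#' individuals over the null expectation, summarise the autoantibody panel,
#' IAA by insulin-treatment duration, and LOD-coded C-peptide per group,
#' compute birthweight z-scores and the z-vs-age-at-diagnosis regression in
#' the high-score group, and run the between-group comparison tests. All
#' inputs are validated before any output is written.
#'
#' @param config A list, or path to a YAML file, with elements:
#'   `weights` (TSV path), `vcf` (VCF path), `phenotypes` (CSV path),
#'   `growth_reference` (CSV path), and either `threshold` (fixed numeric)
#'   or `reference_scores` (CSV path with a `grs` column, thresholded at
#'   `centile`, default 0.95); optional `alpha` (default `1 - centile`),
#'   `cohort_total` (default: number scored), `strand_policy`.
#' @param outdir If non-`NULL`, writes `report.json`, `scores.csv`,
#'   per-group summary CSVs and a `log.txt` there.
#' @param write_figures Also write the four standard figures (PDF) to
#'   `outdir`.
#' @return A `t1d_report` object (list); see [print.t1d_report()].
#' @export
run_t1d_pipeline <- function(config, outdir = NULL, write_figures = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (f in c("weights", "vcf", "phenotypes", "growth_reference")) {
    if (is.null(config[[f]])) abort(paste0("config is missing '", f, "'"))
    if (!file.exists(config[[f]])) abort(paste0("input file not found: ", config[[f]]))
  }
  centile <- config$centile %||% 0.95
  alpha <- config$alpha %||% (1 - centile)
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  weights <- read_weight_table(config$weights)
  pheno <- readr::read_csv(config$phenotypes, col_types = readr::cols(
    individual_id = readr::col_character(), group = readr::col_character(),
    sex = readr::col_character(), cpeptide_pmol_l = readr::col_character(),
    .default = readr::col_double()
  ))
  bad_groups <- setdiff(unique(pheno$group), pipeline_groups)
  if (length(bad_groups) > 0) {
    abort(paste0("unrecognised group(s) in phenotype table: ",
                 paste(bad_groups, collapse = ", "),
                 " (allowed: ", paste(pipeline_groups, collapse = ", "), ")"))
  }
  if (anyDuplicated(pheno$individual_id)) abort("duplicate individual_id in phenotypes")
  growth_ref <- read_growth_reference(config$growth_reference)

  # --- score ---
  dosages <- dosages_from_vcf(config$vcf, weights,
                              strand_policy = config$strand_policy %||% "strict")
  scores <- compute_grs(dosages, weights)
  note("scored ", nrow(scores), " individuals at ", nrow(weights), " SNPs")

  # --- classify ---
  if (!is.null(config$threshold)) {
    threshold <- as.numeric(config$threshold)
    note("using fixed threshold ", threshold)
  } else {
    if (is.null(config$reference_scores)) {
      abort("config needs either 'threshold' or 'reference_scores'")
    }
    ref <- readr::read_csv(config$reference_scores,
                           col_types = readr::cols(grs = readr::col_double()))
    threshold <- ref_centile(ref$grs, centile)
    note("threshold ", signif(threshold, 4), " = ", centile * 100,
         "th centile of ", nrow(ref), " reference scores")
  }
  scores <- classify_high_low(scores, threshold)

  # --- join, derive groups ---
  unknown_ids <- pheno$individual_id[pheno$group == "unknown"]
  missing_geno <- setdiff(unknown_ids, scores$individual_id)
  if (length(missing_geno) > 0) {
    abort(paste0("unknown-group individual(s) without genotypes: ",
                 paste(head(missing_geno, 5), collapse = ", ")))
  }
  cohort <- dplyr::left_join(pheno, scores, by = "individual_id") |>
    dplyr::mutate(group = dplyr::case_when(
      .data$group == "unknown" & .data$label == "high" ~ "unknown_high_GRS",
      .data$group == "unknown" ~ "unknown_low_GRS",
      TRUE ~ .data$group
    ))

  # --- excess ---
  n_tested <- length(unknown_ids)
  excess <- NULL
  if (n_tested > 0) {
    n_high <- sum(cohort$group == "unknown_high_GRS")
    excess <- estimate_excess(n_high, n_tested, alpha,
                              config$cohort_total %||% n_tested)
    note("excess: observed ", proportion_report(n_high, n_tested),
         ", expected ", excess$expected_rounded)
  } else {
    note("no unknown-group individuals; excess stage skipped")
  }

  # --- biomarker summaries ---
  ab <- antibody_long(cohort)
  panel <- summarize_panel(ab)
  iaa <- iaa_duration_summary(ab)
  cpep <- cpeptide_group_summary(cohort)

  # --- clinical ---
  cohort <- birthweight_z(cohort, growth_ref)
  regression <- NULL
  high <- dplyr::filter(cohort, .data$group == "unknown_high_GRS",
                        !is.na(.data$birthweight_z),
                        !is.na(.data$age_at_diagnosis_weeks))
  if (nrow(high) >= 3 && length(unique(high$age_at_diagnosis_weeks)) > 1) {
    regression <- regress_z_on_age(high)
  } else {
    note("fewer than 3 usable high-GRS birthweight records; regression skipped")
  }

  group_summaries <- cohort |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      grs = list(if (any(!is.na(.data$grs))) median_iqr(.data$grs) else NULL),
      age = list(median_iqr(.data$age_at_diagnosis_weeks)),
      birthweight_z = list(median_iqr(.data$birthweight_z)),
      .groups = "drop"
    ) |>
    tidyr::unnest(c("grs", "age", "birthweight_z"), names_sep = "_")

  tests <- pipeline_tests(cohort, panel, iaa)
  note("ran ", nrow(tests), " between-group tests; threshold for significance p < 0.05")

  report <- structure(list(
    threshold = threshold, alpha = alpha, scores = scores, cohort = cohort,
    excess = excess, group_summaries = group_summaries, panel = panel,
    iaa = iaa, cpeptide = cpep, regression = regression, tests = tests,
    log = log_lines
  ), class = "t1d_report")

  if (!is.null(outdir)) write_report(report, outdir, write_figures)
  report
}

# canonical between-group comparisons, each tagged with its test and n
pipeline_tests <- function(cohort, panel, iaa) {
  rows <- list()
  add <- function(test, comparison, g1, g2, n1, n2, statistic, p) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      test = test, comparison = comparison, group1 = g1, group2 = g2,
      n1 = n1, n2 = n2, statistic = statistic, p = p, sidedness = "two-sided")
  }
  panel_pair <- function(g1, g2) {
    p1 <- panel[panel$group == g1, ]; p2 <- panel[panel$group == g2, ]
    if (nrow(p1) == 1 && nrow(p2) == 1) {
      ft <- fisher_exact(p1$n_any_positive, p1$n_measured - p1$n_any_positive,
                         p2$n_any_positive, p2$n_measured - p2$n_any_positive)
      add("fisher_exact", "any islet autoantibody positive", g1, g2,
          p1$n_measured, p2$n_measured, NA_real_, ft$p)
    }
  }
  panel_pair("unknown_high_GRS", "monogenic_NDM")
  panel_pair("unknown_high_GRS", "T1D_6_24m")

  short <- iaa[iaa$stratum == "short", ]
  s1 <- short[short$group == "unknown_high_GRS", ]
  s2 <- short[short$group == "monogenic_NDM", ]
  if (nrow(s1) == 1 && nrow(s2) == 1) {
    ft <- fisher_exact(s1$n_positive, s1$n - s1$n_positive,
                       s2$n_positive, s2$n - s2$n_positive)
    add("fisher_exact", "IAA positive, insulin duration <= 13 weeks",
        "unknown_high_GRS", "monogenic_NDM", s1$n, s2$n, NA_real_, ft$p)
  }

  cpep_vals <- function(g) {
    x <- cohort[cohort$group == g & !is.na(cohort$diabetes_duration_months) &
                  cohort$diabetes_duration_months < 12, ]
    code_cpeptide(x$cpeptide_pmol_l)
  }
  for (g2 in c("monogenic_NDM", "T1D_6_24m")) {
    x <- cpep_vals("unknown_high_GRS"); y <- cpep_vals(g2)
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) > 0 && length(y) > 0) {
      mw <- mann_whitney_u(x, y)
      add("mann_whitney_u", "C-peptide, diabetes duration < 12 months",
          "unknown_high_GRS", g2, length(x), length(y), mw$U, mw$p)
    }
  }

  grs_groups <- split(cohort$grs[!is.na(cohort$grs)],
                      cohort$group[!is.na(cohort$grs)])
  grs_groups <- grs_groups[lengths(grs_groups) > 0]
  if (length(grs_groups) >= 2) {
    kw <- kruskal_wallis(unname(grs_groups))
    rows[[length(rows) + 1]] <- tibble::tibble(
      test = "kruskal_wallis", comparison = "GRS across scored groups",
      group1 = paste(names(grs_groups), collapse = "+"), group2 = NA_character_,
      n1 = sum(lengths(grs_groups)), n2 = NA_integer_,
      statistic = kw$H, p = kw$p, sidedness = "two-sided")
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) out$significant <- out$p < 0.05
  out
}

write_report <- function(report, outdir, write_figures) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  json <- list(
    threshold = report$threshold, alpha = report$alpha,
    excess = if (!is.null(report$excess)) as.list(tidy(report$excess)),
    group_summaries = report$group_summaries,
    panel = report$panel, iaa = report$iaa, cpeptide = report$cpeptide,
    regression = if (!is.null(report$regression)) as.list(glance(report$regression)),
    tests = report$tests
  )
  jsonlite::write_json(json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  readr::write_csv(report$scores, file.path(outdir, "scores.csv"))
  readr::write_csv(report$group_summaries, file.path(outdir, "group_summaries.csv"))
  readr::write_csv(report$panel, file.path(outdir, "panel_summary.csv"))
  readr::write_csv(report$cpeptide, file.path(outdir, "cpeptide_summary.csv"))
  writeLines(c(paste0("# run at ", format(Sys.time(), usetz = TRUE)), report$log),
             file.path(outdir, "log.txt"))
  if (write_figures) {
    save_fig <- function(p, name) {
      if (!is.null(p)) ggplot2::ggsave(file.path(outdir, name), p,
                                       width = 6, height = 4, device = "pdf")
    }
    refs <- NULL
    save_fig(plot_grs_distribution(report$scores, threshold = report$threshold),
             "grs_distribution.pdf")
    save_fig(plot_antibody_panel(report$panel), "antibody_panel.pdf")
    save_fig(plot_cpeptide_groups(report$cohort), "cpeptide.pdf")
    if (!is.null(report$regression)) {
      save_fig(autoplot(report$regression), "birthweight_z_vs_age.pdf")
    }
  }
  invisible(outdir)
}

#' @export
print.t1d_report <- function(x, ...) {
  cat("T1D polygenic-risk analysis report\n")
  cat("  threshold: ", signif(x$threshold, 4), " (null exceedance alpha = ",
      x$alpha, ")\n", sep = "")
  if (!is.null(x$excess)) {
    cat("  high GRS: ", proportion_report(x$excess$n_high, x$excess$n_tested),
        "; expected ", x$excess$expected_rounded, "; excess ", x$excess$excess,
        "; cohort fraction ",
        proportion_report(x$excess$excess, x$excess$cohort_total),
        "; binomial p ", format(x$excess$binomial_p, digits = 3), "\n", sep = "")
  }
  if (nrow(x$panel) > 0) {
    cat("  any-autoantibody-positive by group:\n")
    for (i in seq_len(nrow(x$panel))) {
      cat("    ", x$panel$group[i], ": ",
          proportion_report(x$panel$n_any_positive[i], x$panel$n_measured[i]),
          "\n", sep = "")
    }
  }
  if (!is.null(x$regression)) {
    cat(sprintf("  birthweight z vs age (high GRS): slope %.3f, r^2 = %.2f, p = %.3g\n",
                x$regression$slope, x$regression$r_squared, x$regression$p_value))
  }
  cat("  tests run: ", nrow(x$tests), " (flagged significant at p < 0.05: ",
      sum(x$tests$significant %||% FALSE), ")\n", sep = "")
  invisible(x)
}
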