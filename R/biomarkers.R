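#' Call autoantibody positivity against a control-derived cut-off
#'
#' A titre is positive when it strictly exceeds the cut-off, which is defined
#' as the 99th percentile of a healthy control population: a titre exactly at
#' the cut-off is negative, keeping the control false-positive rate at or
#' below 1%.
#'
#' @param titre Non-negative assay titre(s).
#' @param cutoff Positive cut-off(s), recycled against `titre`.
#' @return Logical vector; `NA` titres give `NA` calls.
#' @export
call_positive <- function(titre, cutoff) {
  if (any(titre < 0, na.rm = TRUE)) abort("titres must be non-negative")
  if (any(cutoff <= 0, na.rm = TRUE)) abort("cut-offs must be positive")
  titre > cutoff
}

#' Pivot wide per-analyte phenotype columns to long form
#'
#' The phenotype CSV stores one `<analyte>_titre` and `<analyte>_cutoff`
#' column pair per analyte; the summaries work on a long table of one row
#' per (individual, analyte) measurement. Rows with a missing titre (analyte
#' not measured for that individual) are dropped.
#'
#' @param pheno Phenotype tibble with `individual_id` and titre/cutoff pairs.
#' @param analytes Analyte names to collect.
#' @param keep Extra columns to carry along (e.g. `group`, durations).
#' @return Long tibble: carried columns plus `analyte`, `titre`, `cutoff`.
#' @export
antibody_long <- function(pheno, analytes = c("GADA", "IA2A", "ZnT8A", "IAA"),
                          keep = intersect(c("group", "insulin_duration_weeks"),
                                           names(pheno))) {
  present <- analytes[paste0(analytes, "_titre") %in% names(pheno)]
  if (length(present) == 0) abort("no <analyte>_titre columns found")
  rows <- purrr::map(present, function(a) {
    tibble::tibble(
      pheno[, c("individual_id", keep), drop = FALSE],
      analyte = a,
      titre = as.numeric(pheno[[paste0(a, "_titre")]]),
      cutoff = as.numeric(pheno[[paste0(a, "_cutoff")]])
    )
  })
  dplyr::filter(dplyr::bind_rows(rows), !is.na(.data$titre))
}

#' Summarise the islet autoantibody panel by group
#'
#' Counts, per group, individuals positive for at least one, at least two,
#' and all three of the panel analytes (GADA, IA2A, ZnT8A by default), plus
#' per-analyte positive counts. Individuals measured for only a subset of
#' analytes are counted from their observed analytes: they enter the
#' any-positive denominator and each measured analyte's denominator. IAA is
#' deliberately not part of the default panel, because antibodies to
#' exogenous insulin cannot be distinguished from autoantibodies in
#' insulin-treated infants; use [iaa_duration_summary()] for IAA.
#'
#' @param calls Long measurement tibble (see [antibody_long()]) with columns
#'   `individual_id`, `analyte`, `titre`, `cutoff` and the grouping column.
#' @param analytes Panel analytes (default GADA, IA2A, ZnT8A).
#' @param group_col Name of the grouping column (default `"group"`).
#' @return Per-group tibble with panel counts/proportions and nested
#'   per-analyte counts in columns `<analyte>_pos` / `<analyte>_n`.
#' @export
summarize_panel <- function(calls, analytes = c("GADA", "IA2A", "ZnT8A"),
                            group_col = "group") {
  calls <- dplyr::filter(calls, .data$analyte %in% analytes)
  if (nrow(calls) == 0) {
    return(tibble::tibble("{group_col}" := character(), n_measured = integer(),
                          n_any_positive = integer(), n_two_positive = integer(),
                          n_three_positive = integer()))
  }
  dup <- dplyr::count(calls, .data$individual_id, .data$analyte) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate (individual, analyte) measurement(s): ",
                 paste(paste(dup$individual_id, dup$analyte), collapse = ", ")))
  }
  calls <- dplyr::mutate(calls, positive = call_positive(.data$titre, .data$cutoff))

  per_ind <- calls |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_col, "individual_id")))) |>
    dplyr::summarise(n_pos = sum(.data$positive), .groups = "drop")

  panel <- per_ind |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_col))) |>
    dplyr::summarise(
      n_measured = dplyr::n(),
      n_any_positive = sum(.data$n_pos >= 1),
      n_two_positive = sum(.data$n_pos >= 2),
      n_three_positive = sum(.data$n_pos >= 3),
      .groups = "drop"
    ) |>
    dplyr::mutate(prop_any_positive = .data$n_any_positive / .data$n_measured)

  per_analyte <- calls |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_col, "analyte")))) |>
    dplyr::summarise(pos = sum(.data$positive), n = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "analyte",
                       values_from = c("pos", "n"),
                       names_glue = "{analyte}_{.value}",
                       values_fill = 0L)
  dplyr::left_join(panel, per_analyte, by = group_col)
}

#' Insulin-autoantibody positivity stratified by insulin-treatment duration
#'
#' IAA positivity is summarised separately from the panel and split at a
#' treatment-duration boundary (default 13 weeks, i.e. about 3 months),
#' because antibodies to injected insulin accumulate with exposure: a short
#' treatment duration is where endogenous insulin autoimmunity is
#' informative. The boundary is inclusive on the short stratum.
#'
#' @param calls Long measurement tibble restricted to or containing IAA rows,
#'   with `insulin_duration_weeks`.
#' @param boundary_weeks Stratum boundary in weeks (default 13).
#' @param group_col Grouping column name.
#' @return Tibble per group x stratum (`"short"` = duration <= boundary,
#'   `"long"`) with `n`, `n_positive`, `proportion`.
#' @export
iaa_duration_summary <- function(calls, boundary_weeks = 13, group_col = "group") {
  calls <- dplyr::filter(calls, .data$analyte == "IAA")
  no_dur <- is.na(calls$insulin_duration_weeks)
  if (any(no_dur)) {
    warn(paste0("excluding ", sum(no_dur),
                " IAA measurement(s) with missing insulin duration"))
    calls <- calls[!no_dur, , drop = FALSE]
  }
  calls |>
    dplyr::mutate(
      positive = call_positive(.data$titre, .data$cutoff),
      stratum = ifelse(.data$insulin_duration_weeks <= boundary_weeks,
                       "short", "long")
    ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_col, "stratum")))) |>
    dplyr::summarise(n = dplyr::n(), n_positive = sum(.data$positive),
                     .groups = "drop") |>
    dplyr::mutate(proportion = .data$n_positive / .data$n)
}

#' Apply limit-of-detection coding to C-peptide values
#'
#' The assay's limit of detection is 3 pmol/l; values below it (including
#' `"<3"` tokens as exported by the laboratory) are coded as 2.9 pmol/l for
#' statistical analysis. Values at or above the limit pass through
#' unchanged. The coding is idempotent.
#'
#' @param raw Numeric values, or character values where below-LOD results
#'   appear as `"<3"` (any `"<x"` token is treated as below the limit).
#' @param lod Limit of detection in pmol/l (default 3).
#' @param coded_as Value assigned below the limit (default 2.9).
#' @return Numeric vector of coded values.
#' @examples
#' code_cpeptide(c("<3", "1.2", "250"))
#' @export
code_cpeptide <- function(raw, lod = 3, coded_as = 2.9) {
  if (is.character(raw)) {
    below_token <- stringr::str_detect(raw, "^\\s*<")
    val <- suppressWarnings(as.numeric(raw))
    val[which(below_token)] <- coded_as
    raw <- val
  }
  if (any(raw < 0, na.rm = TRUE)) abort("C-peptide values must be non-negative")
  ifelse(!is.na(raw) & raw < lod, coded_as, raw)
}

#' C-peptide summary by group and diabetes duration
#'
#' Medians and interquartile ranges of LOD-coded C-peptide, per group and
#' duration stratum (below vs at/above `boundary_months` since diagnosis),
#' with the fraction of undetectable values (coded at 2.9 pmol/l).
#'
#' @param data Tibble with `cpeptide_pmol_l` (numeric or with `"<3"` tokens),
#'   `diabetes_duration_months`, and the grouping column; rows with a
#'   missing measurement are dropped.
#' @param boundary_months Duration boundary (default 12).
#' @param group_col Grouping column name.
#' @param lod,coded_as Passed to [code_cpeptide()].
#' @return Tibble per group x stratum with `n`, `median`, `q25`, `q75`,
#'   `n_undetectable`, `undetectable_fraction`.
#' @export
cpeptide_group_summary <- function(data, boundary_months = 12,
                                   group_col = "group", lod = 3, coded_as = 2.9) {
  data |>
    dplyr::mutate(coded = code_cpeptide(.data$cpeptide_pmol_l, lod, coded_as)) |>
    dplyr::filter(!is.na(.data$coded), !is.na(.data$diabetes_duration_months)) |>
    dplyr::mutate(stratum = ifelse(.data$diabetes_duration_months < boundary_months,
                                   "under_boundary", "over_boundary")) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_col, "stratum")))) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = median(.data$coded),
      q25 = quantile(.data$coded, 0.25, type = 7, names = FALSE),
      q75 = quantile(.data$coded, 0.75, type = 7, names = FALSE),
      n_undetectable = sum(.data$coded == coded_as),
      .groups = "drop"
    ) |>
    dplyr::mutate(undetectable_fraction = .data$n_undetectable / .data$n)
}
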