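#' Histogram of cohort scores against the reference distribution
#'
#' Mirrors the canonical view of the analysis: the referral cohort's score
#' histogram with the control reference density and the centile threshold
#' as a dashed line; cohort mass to the right of the line beyond what the
#' reference curve predicts is the polygenic enrichment.
#'
#' @param scores Score tibble with a `grs` column.
#' @param reference_scores Optional numeric vector of reference scores.
#' @param threshold Optional threshold to draw.
#' @return A ggplot object.
#' @export
plot_grs_distribution <- function(scores, reference_scores = NULL,
                                  threshold = NULL) {
  p <- ggplot2::ggplot(scores, ggplot2::aes(x = .data$grs)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::labs(x = "genetic risk score", y = "density") +
    ggplot2::theme_minimal()
  if (!is.null(reference_scores)) {
    p <- p + ggplot2::geom_density(
      data = tibble::tibble(grs = reference_scores),
      ggplot2::aes(x = .data$grs), colour = "black", linewidth = 0.8)
  }
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = "dashed")
  }
  p
}

#' Bar chart of autoantibody positivity by group
#'
#' @param panel A [summarize_panel()] result.
#' @return A ggplot object.
#' @export
plot_antibody_panel <- function(panel) {
  analytes <- sub("_pos$", "", grep("_pos$", names(panel), value = TRUE))
  long <- purrr::map_dfr(c(list(c("any", NA)), purrr::map(analytes, c)), function(a) {
    if (a[1] == "any") {
      tibble::tibble(group = panel$group, analyte = "any of panel",
                     proportion = panel$n_any_positive / panel$n_measured)
    } else {
      tibble::tibble(group = panel$group, analyte = a[1],
                     proportion = panel[[paste0(a[1], "_pos")]] /
                       panel[[paste0(a[1], "_n")]])
    }
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$proportion,
                                     fill = .data$analyte)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "positive", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Box plot of LOD-coded C-peptide by group
#'
#' C-peptide on a log scale with the 3 pmol/l limit of detection drawn;
#' values below the limit sit at the 2.9 pmol/l coding value.
#'
#' @param cohort Tibble with `group` and `cpeptide_pmol_l` columns.
#' @param lod Limit of detection (default 3).
#' @return A ggplot object.
#' @export
plot_cpeptide_groups <- function(cohort, lod = 3) {
  d <- cohort |>
    dplyr::mutate(coded = code_cpeptide(.data$cpeptide_pmol_l, lod)) |>
    dplyr::filter(!is.na(.data$coded))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$coded)) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::geom_hline(yintercept = lod, linetype = "dotted") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "C-peptide (pmol/l, log scale)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Scatter of birthweight z-score against age at diagnosis with the OLS fit
#'
#' @param object A [regress_z_on_age()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bwz_fit
#' @export
autoplot.bwz_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$age, y = .data$z)) +
    ggplot2::geom_point(shape = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "black",
                         linewidth = 0.7) +
    ggplot2::labs(
      x = "age at diagnosis (weeks)", y = "birthweight z-score",
      subtitle = sprintf("r² = %.2f, p = %.3g (n = %d)",
                         object$r_squared, object$p_value, object$n)) +
    ggplot2::theme_minimal()
}
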