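#' Centile of a control reference distribution
#'
#' Quantile of a reference score sample under the linear-interpolation
#' convention (type 7): the cut-point used to define "high" genetic risk.
#' A warning is issued for tail centiles (q >= 0.95) estimated from fewer
#' than 20 reference scores.
#'
#' @param scores Numeric vector of reference scores (finite, non-empty).
#' @param q Quantile level in (0, 1); the study uses 0.95.
#' @return The threshold as a single number.
#' @export
ref_centile <- function(scores, q) {
  if (length(scores) == 0) abort("reference scores must be non-empty")
  if (any(!is.finite(scores))) abort("reference scores must be finite")
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 1) {
    abort("q must be a single number strictly inside (0, 1)")
  }
  if (q >= 0.95 && length(scores) < 20) {
    warn("fewer than 20 reference scores for a tail centile; threshold will be unstable")
  }
  unname(quantile(scores, q, type = 7, names = FALSE))
}

#' Fraction of scores exceeding a threshold
#'
#' @param scores Numeric vector of scores.
#' @param threshold Cut-point; exceedance is strict (`score > threshold`).
#' @return A one-row tibble with `k` (count above), `n`, and `fraction = k/n`.
#' @export
exceedance_fraction <- function(scores, threshold) {
  if (length(scores) == 0) abort("scores must be non-empty")
  k <- sum(scores > threshold)
  tibble::tibble(k = as.integer(k), n = length(scores),
                 fraction = k / length(scores))
}

#' Excess of high-score individuals over the null expectation
#'
#' Given `n_high` of `n_tested` individuals above a threshold that only a
#' fraction `alpha` of a null (monogenic-like) population would exceed, the
#' excess `n_high - round(alpha * n_tested)` is attributed to a second,
#' genetically enriched subpopulation (polygenic type 1 diabetes). Dividing
#' the excess by the size of the full referral cohort gives a lower bound on
#' the polygenic fraction of that cohort — a lower bound because the
#' enriched class itself does not exceed the threshold with certainty.
#'
#' The expected count is rounded half-to-even before subtraction (both the
#' rounded and unrounded versions are kept); a negative excess is reported
#' as 0 with `deficit = TRUE`. The significance of the observed count under
#' the null is the exact binomial upper tail
#' \eqn{P(X \ge n_{high}), X \sim Bin(n_{tested}, \alpha)}, summed in log
#' space so extreme tails do not underflow to zero.
#'
#' @param n_high Observed count above threshold.
#' @param n_tested Number of individuals scored.
#' @param alpha Null exceedance probability (0.05 for a 95th-centile cut).
#' @param cohort_total Size of the full cohort the excess fraction refers to.
#' @return An object of class `excess_estimate`; see [tidy.excess_estimate()].
#' @examples
#' estimate_excess(63, 166, 0.05, 1438)
#' @export
estimate_excess <- function(n_high, n_tested, alpha = 0.05, cohort_total = n_tested) {
  stopifnot(length(n_high) == 1, length(n_tested) == 1,
            length(alpha) == 1, length(cohort_total) == 1)
  if (n_high < 0 || n_high > n_tested) abort("need 0 <= n_high <= n_tested")
  if (n_tested > cohort_total) abort("need n_tested <= cohort_total")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be strictly inside (0, 1)")

  expected_real <- alpha * n_tested
  expected_rounded <- as.integer(round(expected_real))
  excess_raw <- n_high - expected_rounded
  deficit <- excess_raw < 0
  excess <- max(0L, as.integer(excess_raw))
  excess_real <- max(0, n_high - expected_real)

  structure(list(
    n_tested = as.integer(n_tested),
    n_high = as.integer(n_high),
    alpha = alpha,
    expected_real = expected_real,
    expected_rounded = expected_rounded,
    excess = excess,
    excess_real = excess_real,
    deficit = deficit,
    cohort_total = as.integer(cohort_total),
    observed_fraction = n_high / n_tested,
    excess_fraction_total = excess / cohort_total,
    excess_fraction_total_real = excess_real / cohort_total,
    excess_fraction_tested = excess / n_tested,
    excess_fraction_tested_real = (n_high - expected_real) / n_tested,
    binomial_p = binom_upper_tail(n_high, n_tested, alpha)
  ), class = "excess_estimate")
}

# exact upper tail P(X >= k), X ~ Binomial(n, p), by log-space summation
binom_upper_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  logs <- dbinom(k:n, n, p, log = TRUE)
  mx <- max(logs)
  min(1, exp(mx + log(sum(exp(logs - mx)))))
}

#' @export
print.excess_estimate <- function(x, ...) {
  cat("Excess over expected above threshold\n")
  cat("  observed: ", proportion_report(x$n_high, x$n_tested), "\n", sep = "")
  cat("  expected under null (alpha = ", format(x$alpha), "): ",
      x$expected_rounded, " (", format(round(x$expected_real, 2)), ")\n", sep = "")
  if (x$deficit) cat("  no excess (observed below expected)\n")
  cat("  excess: ", x$excess, "; as fraction of cohort (n = ", x$cohort_total,
      "): ", proportion_report(x$excess, x$cohort_total), "\n", sep = "")
  cat("  exact binomial upper-tail p: ", format(x$binomial_p, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Tidy an excess estimate
#'
#' @param x An `excess_estimate`.
#' @param ... Unused.
#' @return One-row tibble of all estimate fields.
#' @method tidy excess_estimate
#' @export
tidy.excess_estimate <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c(
    "n_tested", "n_high", "alpha", "expected_real", "expected_rounded",
    "excess", "excess_real", "deficit", "cohort_total", "observed_fraction",
    "excess_fraction_total", "excess_fraction_total_real",
    "excess_fraction_tested", "excess_fraction_tested_real", "binomial_p"
  )])
}

#' @rdname tidy.excess_estimate
#' @method glance excess_estimate
#' @export
glance.excess_estimate <- function(x, ...) {
  tibble::tibble(excess = x$excess,
                 excess_fraction_total = x$excess_fraction_total,
                 binomial_p = x$binomial_p)
}

#' Confidence interval for the excess fraction
#'
#' Wilson score interval for the exceedance probability
#' `p_high = n_high / n_tested`, mapped to the excess-fraction-of-cohort
#' scale as `(p - alpha) * n_tested / cohort_total` and floored at 0.
#'
#' @param est An [estimate_excess()] result.
#' @param level Coverage level in (0, 1), default 0.95.
#' @return A one-row tibble with `lo` and `hi`.
#' @export
excess_confidence_interval <- function(est, level = 0.95) {
  if (level <= 0 || level >= 1) abort("level must be strictly inside (0, 1)")
  z <- qnorm(1 - (1 - level) / 2)
  n <- est$n_tested
  p <- est$n_high / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  to_excess <- function(ph) max(0, (ph - est$alpha) * n / est$cohort_total)
  tibble::tibble(lo = to_excess(centre - half), hi = to_excess(centre + half))
}
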