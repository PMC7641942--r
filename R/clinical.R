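#' Read a birthweight growth reference
#'
#' A growth reference maps (sex, gestational week) to the mean and standard
#' deviation of birthweight in grams. Real analyses plug in published
#' reference ranges (e.g. the WHO international tables); the package ships a
#' clearly labelled synthetic reference for examples and tests
#' (`system.file("extdata", "synthetic_growth_reference.csv", package = "earlyt1d")`).
#'
#' @param path CSV with columns `sex` (`"female"`/`"male"`),
#'   `gestational_week`, `mean_g`, `sd_g`.
#' @return A validated tibble sorted by sex and week.
#' @export
read_growth_reference <- function(path) {
  ref <- readr::read_csv(path, col_types = readr::cols(
    sex = readr::col_character(),
    gestational_week = readr::col_double(),
    mean_g = readr::col_double(),
    sd_g = readr::col_double()
  ))
  validate_growth_reference(ref)
}

validate_growth_reference <- function(ref) {
  required <- c("sex", "gestational_week", "mean_g", "sd_g")
  missing_cols <- setdiff(required, names(ref))
  if (length(missing_cols) > 0) {
    abort(paste0("growth reference is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!all(ref$sex %in% c("female", "male"))) {
    abort("growth reference sex must be 'female' or 'male'")
  }
  if (any(ref$sd_g <= 0)) abort("growth reference sd_g must be positive everywhere")
  ref <- dplyr::arrange(ref, .data$sex, .data$gestational_week)
  non_increasing <- ref |>
    dplyr::group_by(.data$sex) |>
    dplyr::summarise(ok = all(diff(.data$mean_g) > 0), .groups = "drop")
  if (!all(non_increasing$ok)) {
    warn("growth reference mean_g is not strictly increasing in gestational week")
  }
  ref
}

#' Birthweight z-scores adjusted for sex and gestational age
#'
#' Standardises each birthweight by the reference mean and SD for the
#' infant's sex and gestational age:
#' `z = (birthweight - mean(sex, week)) / sd(sex, week)`. Mean and SD are
#' linearly interpolated between tabulated integer weeks; gestational ages
#' outside the tabulated range are an error (no extrapolation).
#'
#' @param data Tibble with columns `birthweight_g`, `gestational_age_weeks`,
#'   `sex`; rows with any of these missing get `NA`.
#' @param ref Growth reference from [read_growth_reference()].
#' @return `data` with an added numeric column `birthweight_z`.
#' @export
birthweight_z <- function(data, ref) {
  ref <- validate_growth_reference(ref)
  z <- rep(NA_real_, nrow(data))
  for (s in unique(data$sex[!is.na(data$sex)])) {
    rs <- ref[ref$sex == s, ]
    if (nrow(rs) == 0) abort(paste0("growth reference has no rows for sex '", s, "'"))
    idx <- which(!is.na(data$sex) & data$sex == s &
                   !is.na(data$gestational_age_weeks) & !is.na(data$birthweight_g))
    if (length(idx) == 0) next
    ga <- data$gestational_age_weeks[idx]
    rng <- range(rs$gestational_week)
    if (any(ga < rng[1] | ga > rng[2])) {
      abort(paste0("gestational age outside the reference range [", rng[1], ", ",
                   rng[2], "] weeks for sex '", s, "'; no extrapolation"))
    }
    mu <- approx(rs$gestational_week, rs$mean_g, xout = ga)$y
    sd <- approx(rs$gestational_week, rs$sd_g, xout = ga)$y
    z[idx] <- (data$birthweight_g[idx] - mu) / sd
  }
  dplyr::mutate(data, birthweight_z = z)
}

#' Invert a z-score back to grams
#'
#' Used by the synthetic-cohort generator to produce birthweights whose
#' z-scores against the shipped reference are exactly the simulated values.
#'
#' @param z,sex,gestational_age_weeks Parallel vectors.
#' @param ref Growth reference.
#' @return Birthweights in grams.
#' @export
birthweight_from_z <- function(z, sex, gestational_age_weeks, ref) {
  ref <- validate_growth_reference(ref)
  out <- rep(NA_real_, length(z))
  for (s in unique(sex)) {
    rs <- ref[ref$sex == s, ]
    idx <- which(sex == s)
    mu <- approx(rs$gestational_week, rs$mean_g, xout = gestational_age_weeks[idx])$y
    sd <- approx(rs$gestational_week, rs$sd_g, xout = gestational_age_weeks[idx])$y
    out[idx] <- mu + z[idx] * sd
  }
  out
}

#' Regress birthweight z-score on age at diagnosis
#'
#' Ordinary least squares of z-score on age at diagnosis in weeks. In very
#' early-onset type 1 diabetes a positive slope (lower birthweight with
#' earlier diagnosis) is the signature of reduced insulin-mediated fetal
#' growth preceding clinical onset.
#'
#' @param data Tibble containing the two variables; rows with missing values
#'   are dropped.
#' @param z_col,age_col Column names (defaults `birthweight_z`,
#'   `age_at_diagnosis_weeks`).
#' @return A `bwz_fit` object with `slope`, `intercept`, `r_squared`,
#'   `p_value` (two-sided t-test on the slope, n - 2 df) and `n`; supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
regress_z_on_age <- function(data, z_col = "birthweight_z",
                             age_col = "age_at_diagnosis_weeks") {
  d <- tibble::tibble(age = as.numeric(data[[age_col]]),
                      z = as.numeric(data[[z_col]]))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 3) abort("need at least 3 complete (age, z) pairs")
  if (length(unique(d$age)) < 2) abort("degenerate design: all ages equal")
  fit <- lm(z ~ age, data = d)
  sm <- summary(fit)
  r2 <- sm$r.squared
  pv <- sm$coefficients["age", "Pr(>|t|)"]
  if (!is.finite(r2)) r2 <- 0      # constant response: no variance to explain
  if (!is.finite(pv)) pv <- NA_real_
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = r2,
    p_value = pv,
    n = nrow(d),
    data = d,
    lm = fit
  ), class = "bwz_fit")
}

#' @export
print.bwz_fit <- function(x, ...) {
  cat("Birthweight z-score vs age at diagnosis (OLS, n = ", x$n, ")\n", sep = "")
  cat(sprintf("  slope %.4f z/week, intercept %.3f, r^2 = %.3f, p = %.4g\n",
              x$slope, x$intercept, x$r_squared, x$p_value))
  invisible(x)
}

#' Tidy a birthweight regression fit
#'
#' @param x A `bwz_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per coefficient; `glance()`: one-row model summary.
#' @method tidy bwz_fit
#' @export
tidy.bwz_fit <- function(x, ...) {
  sm <- summary(x$lm)$coefficients
  tibble::tibble(
    term = c("intercept", "age_at_diagnosis_weeks"),
    estimate = c(x$intercept, x$slope),
    std_error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p_value = unname(sm[, "Pr(>|t|)"])
  )
}

#' @rdname tidy.bwz_fit
#' @method glance bwz_fit
#' @export
glance.bwz_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, p_value = x$p_value, n = x$n,
                 slope = x$slope, intercept = x$intercept)
}
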