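#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test by enumeration of the hypergeometric support with
#' the table margins fixed: the p-value is the sum of the probabilities of
#' every table whose probability does not exceed that of the observed table
#' (with a relative tolerance of 1e-7 to absorb floating-point ties).
#' Probabilities are evaluated in log space.
#'
#' @param a,b,c,d Cell counts, rows = groups, columns = outcome
#'   positive/negative. Alternatively `a` may be a 2x2 matrix.
#' @return A one-row tibble with `p` and `odds_ratio_sample` (the ad/bc
#'   cross-product ratio, `Inf`/`NaN` allowed for zero cells).
#' @examples
#' fisher_exact(9, 13, 7, 86)  # antibody positivity, high-GRS vs monogenic
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("cell counts must be non-negative integers")
  }
  if (sum(cells) == 0) abort("empty table")
  m <- a + c          # column-1 margin
  n <- b + d          # column-2 margin
  k <- a + b          # row-1 margin
  support <- max(0, k - n):min(k, m)
  logp <- dhyper(support, m, n, k, log = TRUE)
  obs <- dhyper(a, m, n, k, log = TRUE)
  keep <- logp <= obs + log1p(1e-7)
  p <- min(1, sum(exp(logp[keep])))
  tibble::new_tibble(list(p = p, odds_ratio_sample = (a * d) / (b * c)), nrow = 1L)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. U is computed from midranks. The
#' p-value is exact (from the null distribution of U) when `n * m <= 400`
#' and there are no ties; otherwise a normal approximation with tie
#' correction and continuity correction is used. Two-sided throughout.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param mode `"auto"` (default: exact when small and tie-free), `"exact"`
#'   (refuses ties, falling back to normal with a message), or `"normal"`.
#' @return One-row tibble with `U` (for the first sample), `p`, and `method`.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  has_ties <- any(duplicated(c(x, y)))

  use_exact <- switch(mode,
    auto = n * m <= 400 && !has_ties,
    exact = {
      if (has_ties) inform("ties present; exact Mann-Whitney p is unavailable, using normal approximation")
      !has_ties
    },
    normal = FALSE
  )

  if (use_exact) {
    # exact two-sided p from the null distribution of U
    if (u > n * m / 2) {
      p <- min(1, 2 * (1 - pwilcox(u - 1, n, m)))
    } else {
      p <- min(1, 2 * pwilcox(u, n, m))
    }
    method <- "exact"
  } else {
    mu <- n * m / 2
    nt <- n + m
    tie_tab <- table(r)
    sigma2 <- (n * m / 12) * (nt + 1 - sum(tie_tab^3 - tie_tab) / (nt * (nt - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal"
  }
  tibble::tibble(U = u, p = p, method = method)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic across two or more groups, with a chi-square
#' p-value on k - 1 degrees of freedom.
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return One-row tibble with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) abort("need at least 2 groups")
  if (any(lengths(groups) == 0)) abort("all groups must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) sum(ri)^2 / length(ri))) - 3 * (n + 1)
  tie_tab <- table(x)
  correction <- 1 - sum(tie_tab^3 - tie_tab) / (n^3 - n)
  if (correction == 0) {
    h <- 0                     # all observations identical
  } else {
    h <- h / correction
  }
  df <- length(groups) - 1
  tibble::tibble(H = h, df = df, p = pchisq(h, df, lower.tail = FALSE))
}

#' Median and interquartile range
#'
#' Quantiles under the same linear-interpolation (type 7) convention as
#' [ref_centile()], the convention used for every reported median (IQR).
#'
#' @param values Non-empty numeric vector.
#' @return One-row tibble with `median`, `q25`, `q75`, `n`.
#' @export
median_iqr <- function(values) {
  if (length(values) == 0) abort("values must be non-empty")
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("values are all missing")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(median = q[2], q25 = q[1], q75 = q[3], n = length(values))
}
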