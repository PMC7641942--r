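# Independent oracles, kept deliberately naive and separate from the
# implementations they check.

# per-allele enumeration: list all 2m allele slots, give each copy of the
# effect allele its SNP weight and 0 otherwise, and average over the slots
# of non-missing SNPs
oracle_grs_one <- function(dosage_row, weights_vec) {
  slots <- c()
  for (i in seq_along(dosage_row)) {
    d <- dosage_row[i]
    if (is.na(d)) next
    slots <- c(slots, rep(weights_vec[i], d), rep(0, 2 - d))
  }
  mean(slots)
}

# sort-and-interpolate quantile (type 7 convention, written from its
# definition rather than via quantile())
oracle_quantile <- function(x, q) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# exhaustive two-sided Fisher p over the full hypergeometric support,
# probabilities from binomial coefficients directly
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  support <- max(0, c1 - r2):min(c1, r1)
  prob <- exp(lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1))
  obs <- prob[support == a]
  min(1, sum(prob[prob <= obs * (1 + 1e-7)]))
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_mwu_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x); m <- length(y)
  idx <- utils::combn(n + m, n)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  us <- apply(idx, 2, function(ii) sum(r[ii]) - n * (n + 1) / 2)
  mean(abs(us - n * m / 2) >= abs(u_obs - n * m / 2) - 1e-9)
}

# direct binomial upper-tail summation (no log space)
oracle_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(stats::dbinom(k:n, n, p))
}

# closed-form normal equations for simple OLS
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  beta <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  alpha <- (sy - beta * sx) / n
  fitted <- alpha + beta * x
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(slope = beta, intercept = alpha, r_squared = r2)
}

toy_path <- function(name) {
  system.file("extdata", name, package = "earlyt1d", mustWork = TRUE)
}

# small deterministic dosage tibble with some missingness
make_dosages <- function(n, weights, p_missing = 0, seed = 1) {
  withr::with_seed(seed, {
    m <- nrow(weights)
    d <- matrix(sample(0:2, n * m, replace = TRUE), nrow = n)
    if (p_missing > 0) d[runif(n * m) < p_missing] <- NA
    colnames(d) <- weights$snp_id
    dplyr::bind_cols(tibble::tibble(individual_id = paste0("i", seq_len(n))),
                     tibble::as_tibble(d))
  })
}
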