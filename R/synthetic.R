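#' Default synthetic SNP weight table
#'
#' Thirty synthetic biallelic SNPs with odds ratios spanning a large
#' HLA-like effect (OR 6.8) down to small effects near 1, the shape typical
#' of a type 1 diabetes risk-allele panel. These are NOT the published
#' score's SNPs or odds ratios (those are user-supplied data); they exist so
#' examples, tests and simulations are self-contained.
#'
#' @return A weight-table tibble (see [weight_table()]).
#' @export
synthetic_weights <- function() {
  ors <- c(6.80, 3.90, 2.30, 1.90, 1.80, 1.70, 1.65, 1.60, 1.55, 1.50,
           1.45, 1.40, 1.38, 1.35, 1.32, 1.30, 1.28, 1.25, 1.23, 1.20,
           1.19, 1.17, 1.15, 1.14, 1.12, 1.11, 1.10, 1.08, 1.06, 1.05)
  pairs <- list(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))
  ea <- vapply(seq_along(ors), function(i) pairs[[(i - 1) %% 4 + 1]][1], "")
  oa <- vapply(seq_along(ors), function(i) pairs[[(i - 1) %% 4 + 1]][2], "")
  weight_table(sprintf("snp%02d", seq_along(ors)), ea, oa, ors)
}

#' Default effect-allele frequencies for the synthetic SNPs
#'
#' Control-population (no-diabetes) effect-allele frequencies in (0.05,
#' 0.62), fixed arbitrarily but deterministically, one per synthetic SNP.
#'
#' @return Numeric vector of length 30.
#' @export
synthetic_allele_freqs <- function() {
  c(0.40, 0.28, 0.55, 0.12, 0.33, 0.47, 0.21, 0.60, 0.09, 0.38,
    0.52, 0.17, 0.44, 0.26, 0.58, 0.14, 0.36, 0.49, 0.23, 0.62,
    0.07, 0.31, 0.54, 0.19, 0.42, 0.27, 0.57, 0.11, 0.35, 0.50)
}

#' Configuration for the synthetic referral cohort
#'
#' Bundles every parameter of the generator: the referral cohort is a
#' mixture of `pi` polygenic type 1 diabetes individuals (odds-ratio-tilted
#' genotypes) and `1 - pi` monogenic-like individuals (control-distributed
#' genotypes), with class-specific antibody positivity, LOD-censored
#' C-peptide, and birthweight z-scores that decline with earlier age at
#' diagnosis. Defaults mirror the study's shape: 30 SNPs, a referral cohort
#' of 166 scored against a reference panel of 4862 controls, and a polygenic
#' fraction of 0.33.
#'
#' @param weights Weight table (default [synthetic_weights()]).
#' @param allele_freqs Control effect-allele frequencies, one per SNP.
#' @param n_reference Control reference panel size (default 4862).
#' @param n_cohort Referral cohort size (default 166).
#' @param pi True polygenic fraction of the cohort in `[0, 1]` (default 0.33).
#' @param n_monogenic_comparator,n_t1d_comparator Sizes of the optional
#'   genotype-free comparator groups written to the phenotype table
#'   (defaults 164 and 152; set to 0 to omit).
#' @param antibody_model Per-class per-analyte positivity probabilities,
#'   assay cut-offs, and titre lognormal spreads.
#' @param cpeptide_model Per-class lognormal parameters plus the 3 pmol/l
#'   limit of detection.
#' @param birthweight_model Per-class `z ~ Normal(mu0 + beta * age_weeks,
#'   sigma)` parameters.
#' @param age_model Per-class age-at-diagnosis distributions (scaled Beta on
#'   (0, 26] weeks for the infant classes; uniform 26-104 weeks for the
#'   older-onset comparator).
#' @param seed Integer seed; a fixed seed makes [simulate_cohort()] output
#'   byte-identical.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(weights = synthetic_weights(),
                       allele_freqs = synthetic_allele_freqs(),
                       n_reference = 4862,
                       n_cohort = 166,
                       pi = 0.33,
                       n_monogenic_comparator = 164,
                       n_t1d_comparator = 152,
                       antibody_model = default_antibody_model(),
                       cpeptide_model = default_cpeptide_model(),
                       birthweight_model = default_birthweight_model(),
                       age_model = default_age_model(),
                       seed = 1L) {
  if (length(allele_freqs) != nrow(weights)) {
    abort("allele_freqs must have one entry per weight-table SNP")
  }
  if (any(allele_freqs <= 0 | allele_freqs >= 1)) {
    abort("allele frequencies must be strictly inside (0, 1)")
  }
  if (pi < 0 || pi > 1) abort("pi must be in [0, 1]")
  if (n_reference < 1 || n_cohort < 1) abort("cohort sizes must be positive")
  structure(list(
    weights = weights, allele_freqs = allele_freqs,
    m = nrow(weights), n_reference = as.integer(n_reference),
    n_cohort = as.integer(n_cohort), pi = pi,
    n_monogenic_comparator = as.integer(n_monogenic_comparator),
    n_t1d_comparator = as.integer(n_t1d_comparator),
    antibody_model = antibody_model, cpeptide_model = cpeptide_model,
    birthweight_model = birthweight_model, age_model = age_model,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_antibody_model <- function() {
  list(
    cutoffs = c(GADA = 11, IA2A = 7.5, ZnT8A = 15, IAA = 5),
    neg_sdlog = 1.0,       # negatives: lognormal with 99th pct at the cutoff
    pos_meanlog = 0.8,     # positives: cutoff * (1 + lognormal(meanlog, sdlog))
    pos_sdlog = 0.6,
    positivity = list(
      polygenic = c(GADA = 0.27, IA2A = 0.18, ZnT8A = 0.14, IAA = 0.82),
      monogenic = c(GADA = 0.02, IA2A = 0.04, ZnT8A = 0.01, IAA = 0.39),
      t1d_6_24m = c(GADA = 0.44, IA2A = 0.15, ZnT8A = 0.08, IAA = 0.60)
    )
  )
}

#' @rdname sim_config
#' @export
default_cpeptide_model <- function() {
  list(lod = 3, coded_as = 2.9,
       polygenic = c(meanlog = log(1.2), sdlog = 1.0),
       monogenic = c(meanlog = log(64), sdlog = 1.2),
       t1d_6_24m = c(meanlog = log(10), sdlog = 1.5))
}

#' @rdname sim_config
#' @export
default_birthweight_model <- function() {
  list(polygenic = c(mu0 = -1.6, beta = 0.05, sigma = 0.77),
       monogenic = c(mu0 = -1.9, beta = 0.05, sigma = 1.0),
       t1d_6_24m = c(mu0 = -0.25, beta = 0.0, sigma = 1.1))
}

#' @rdname sim_config
#' @export
default_age_model <- function() {
  list(polygenic = c(shape1 = 1.8, shape2 = 1.4, max_weeks = 26),
       monogenic = c(shape1 = 1.3, shape2 = 2.2, max_weeks = 26),
       t1d_6_24m = c(min_weeks = 26, max_weeks = 104))
}

#' Simulate control genotypes under Hardy-Weinberg equilibrium
#'
#' Per SNP, dosage ~ Binomial(2, f) independently across SNPs and
#' individuals (linkage equilibrium).
#'
#' @param config A [sim_config()].
#' @param n Number of individuals.
#' @param id_prefix Prefix for generated individual ids.
#' @return Wide dosage tibble compatible with [compute_grs()].
#' @export
simulate_control_genotypes <- function(config, n, id_prefix = "C") {
  m <- config$m
  d <- vapply(seq_len(m), function(i) rbinom(n, 2, config$allele_freqs[i]),
              integer(n))
  if (n == 1) d <- matrix(d, nrow = 1)
  colnames(d) <- config$weights$snp_id
  dplyr::bind_cols(
    tibble::tibble(individual_id = sprintf("%s%05d", id_prefix, seq_len(n))),
    tibble::as_tibble(d)
  )
}

# per-SNP genotype law in cases: Hardy-Weinberg tilted by OR^dosage
case_genotype_probs <- function(f, or) {
  w <- dbinom(0:2, 2, f) * or^(0:2)
  w / sum(w)
}

#' Simulate case genotypes under the odds-ratio tilt
#'
#' Per SNP, `P(dosage = g | case)` is proportional to
#' `choose(2, g) f^g (1-f)^(2-g) OR^g`: the genotype law implied by a
#' logistic risk model with the configured per-allele odds ratios. With all
#' ORs equal to 1 this reduces to the control law.
#'
#' @inheritParams simulate_control_genotypes
#' @export
simulate_case_genotypes <- function(config, n, id_prefix = "P") {
  m <- config$m
  d <- vapply(seq_len(m), function(i) {
    p <- case_genotype_probs(config$allele_freqs[i], config$weights$odds_ratio[i])
    sample.int(3, n, replace = TRUE, prob = p) - 1L
  }, integer(n))
  if (n == 1) d <- matrix(d, nrow = 1)
  colnames(d) <- config$weights$snp_id
  dplyr::bind_cols(
    tibble::tibble(individual_id = sprintf("%s%05d", id_prefix, seq_len(n))),
    tibble::as_tibble(d)
  )
}

#' Exact distribution of the genetic risk score
#'
#' Convolves the 30 (in general m) independent per-SNP dosage-weight
#' distributions numerically to obtain the exact distribution of the score
#' numerator, on a fixed grid: weights are rounded to `resolution` so every
#' partial sum is an exact grid multiple and atoms merge without
#' accumulating error. Used to calibrate the analytic control tail
#' probability and the polygenic-class exceedance sensitivity.
#'
#' @param weights Weight table.
#' @param allele_freqs Control effect-allele frequencies.
#' @param case If `TRUE`, use the odds-ratio-tilted case genotype law.
#' @param resolution Weight grid in score-numerator units (default 1e-6).
#' @return A tibble with columns `grs` (atom) and `prob`, ascending in `grs`.
#' @export
grs_distribution <- function(weights, allele_freqs, case = FALSE,
                             resolution = 1e-6) {
  m <- nrow(weights)
  w_int <- as.integer(round(weights$weight / resolution))
  if (any(w_int < 0)) abort("grs_distribution requires non-negative weights")
  max_int <- sum(2L * w_int)
  p <- numeric(max_int + 1)
  p[1] <- 1
  for (i in seq_len(m)) {
    g_probs <- if (case) {
      case_genotype_probs(allele_freqs[i], weights$odds_ratio[i])
    } else {
      dbinom(0:2, 2, allele_freqs[i])
    }
    newp <- numeric(max_int + 1)
    for (g in 0:2) {
      shift <- g * w_int[i]
      if (g_probs[g + 1] > 0) {
        idx <- seq_len(max_int + 1 - shift)
        newp[idx + shift] <- newp[idx + shift] + p[idx] * g_probs[g + 1]
      }
    }
    p <- newp
  }
  keep <- which(p > 0)
  tibble::tibble(grs = (keep - 1) * resolution / (2 * m), prob = p[keep])
}

#' Tail probability and quantile of a score distribution
#'
#' @param dist A [grs_distribution()] tibble.
#' @param threshold Cut-point; returns `P(score > threshold)` (strict).
#' @return A probability.
#' @export
grs_tail_probability <- function(dist, threshold) {
  sum(dist$prob[dist$grs > threshold])
}

#' @rdname grs_tail_probability
#' @param q Level in (0, 1); returns the smallest atom whose CDF reaches `q`.
#' @export
grs_distribution_quantile <- function(dist, q) {
  cdf <- cumsum(dist$prob)
  dist$grs[which(cdf >= q)[1]]
}
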