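test_that("control genotypes follow Hardy-Weinberg expectations", {
  cfg <- sim_config(allele_freqs = rep(0.3, 30), seed = 101)
  g <- withr::with_seed(101, simulate_control_genotypes(cfg, 10000))
  mean_dosage <- mean(as.matrix(g[, cfg$weights$snp_id]))
  se <- sqrt(2 * 0.3 * 0.7 / (10000 * 30))
  expect_lt(abs(mean_dosage - 0.6), 4 * se)
})

test_that("case genotype law is the odds-ratio tilt", {
  # f = 0.5, OR = 2 -> P(g = 0, 1, 2) = (1, 4, 4) / 9
  w <- weight_table("s1", "A", "G", 2)
  cfg <- sim_config(weights = w, allele_freqs = 0.5, seed = 7,
                    n_monogenic_comparator = 0, n_t1d_comparator = 0)
  g <- withr::with_seed(7, simulate_case_genotypes(cfg, 20000))
  props <- tabulate(g$s1 + 1, 3) / 20000
  expect_equal(props, c(1, 4, 4) / 9, tolerance = 0.02)

  # OR = 1 reduces to the control law
  w1 <- weight_table("s1", "A", "G", 1)
  cfg1 <- sim_config(weights = w1, allele_freqs = 0.4, seed = 8,
                     n_monogenic_comparator = 0, n_t1d_comparator = 0)
  gc <- withr::with_seed(8, simulate_case_genotypes(cfg1, 20000))
  props1 <- tabulate(gc$s1 + 1, 3) / 20000
  expect_equal(props1, dbinom(0:2, 2, 0.4), tolerance = 0.02)
})

test_that("exact score distribution matches simulation and the tilt", {
  w <- synthetic_weights()[1:8, ]
  f <- synthetic_allele_freqs()[1:8]
  dist <- grs_distribution(w, f)
  expect_equal(sum(dist$prob), 1, tolerance = 1e-12)
  expect_true(!is.unsorted(dist$grs))

  cfg <- sim_config(weights = w, allele_freqs = f,
                    n_monogenic_comparator = 0, n_t1d_comparator = 0, seed = 5)
  g <- withr::with_seed(5, simulate_control_genotypes(cfg, 20000))
  s <- compute_grs(g, w)
  t <- grs_distribution_quantile(dist, 0.9)
  expect_equal(mean(s$grs > t), grs_tail_probability(dist, t), tolerance = 0.01)

  case_dist <- grs_distribution(w, f, case = TRUE)
  expect_equal(sum(case_dist$prob), 1, tolerance = 1e-12)
  # risk tilt shifts the case distribution upward
  expect_gt(sum(case_dist$grs * case_dist$prob), sum(dist$grs * dist$prob))
})

test_that("fixed seed makes simulate_cohort byte-identical", {
  cfg <- sim_config(n_cohort = 30, n_reference = 40, seed = 77,
                    n_monogenic_comparator = 5, n_t1d_comparator = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_cohort(cfg, d1)
  simulate_cohort(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("mixture structure: class-conditional score ordering and null calibration", {
  cfg <- sim_config(n_cohort = 400, n_reference = 2000, pi = 0.4, seed = 55,
                    n_monogenic_comparator = 0, n_t1d_comparator = 0)
  sim <- simulate_cohort(cfg)
  scores <- compute_grs(sim$genotypes, cfg$weights)
  joined <- dplyr::left_join(scores, sim$truth, by = "individual_id")
  expect_gt(mean(joined$grs[joined$true_class == "polygenic"]),
            mean(joined$grs[joined$true_class == "monogenic"]))

  # pi = 0: cohort is all monogenic-like, exceedance of the reference 95th
  # centile stays near 0.05
  cfg0 <- sim_config(n_cohort = 1000, n_reference = 3000, pi = 0, seed = 56,
                     n_monogenic_comparator = 0, n_t1d_comparator = 0)
  sim0 <- simulate_cohort(cfg0)
  thr <- ref_centile(sim0$reference_scores$grs, 0.95)
  frac <- exceedance_fraction(compute_grs(sim0$genotypes, cfg0$weights)$grs, thr)
  expect_lt(abs(frac$fraction - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("antibody cut-offs give about 1% positivity in an unenriched class", {
  am <- default_antibody_model()
  am$positivity$monogenic[] <- 0   # remove true positives; leave assay noise
  cfg <- sim_config(n_cohort = 8000, pi = 0, n_reference = 20, seed = 99,
                    antibody_model = am,
                    n_monogenic_comparator = 0, n_t1d_comparator = 0)
  sim <- simulate_cohort(cfg)
  for (analyte in c("GADA", "IA2A", "ZnT8A")) {
    rate <- mean(call_positive(sim$phenotypes[[paste0(analyte, "_titre")]],
                               sim$phenotypes[[paste0(analyte, "_cutoff")]]))
    expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / 8000) + 0.002)
  }
})

test_that("phenotype table carries LOD tokens and valid classes", {
  cfg <- sim_config(n_cohort = 120, n_reference = 30, seed = 12,
                    n_monogenic_comparator = 20, n_t1d_comparator = 20)
  sim <- simulate_cohort(cfg)
  expect_true(any(sim$phenotypes$cpeptide_pmol_l == "<3"))
  expect_setequal(unique(sim$phenotypes$group),
                  c("unknown", "monogenic_NDM", "T1D_6_24m"))
  expect_setequal(unique(sim$truth$true_class), c("polygenic", "monogenic"))
  expect_equal(sum(sim$truth$true_class == "polygenic"), round(0.33 * 120))
  # truth ids are exactly the referral cohort
  expect_setequal(sim$truth$individual_id, sim$genotypes$individual_id)
})

test_that("invalid configurations are rejected before anything is written", {
  expect_error(sim_config(allele_freqs = rep(1.2, 30)), "inside \\(0, 1\\)")
  expect_error(sim_config(pi = 1.5), "pi")
  expect_error(sim_config(allele_freqs = c(0.5, 0.5)), "one entry per")
})
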