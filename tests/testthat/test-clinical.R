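growth_ref <- function() {
  read_growth_reference(toy_path("synthetic_growth_reference.csv"))
}

test_that("z-score is standardisation against the sex/week reference cell", {
  ref <- growth_ref()
  cell <- ref[ref$sex == "male" & ref$gestational_week == 38, ]
  d <- tibble::tibble(
    individual_id = c("a", "b"), sex = "male",
    gestational_age_weeks = 38,
    birthweight_g = c(cell$mean_g, cell$mean_g + cell$sd_g)
  )
  z <- birthweight_z(d, ref)$birthweight_z
  expect_equal(z, c(0, 1))
})

test_that("non-integer weeks interpolate mean and sd linearly", {
  ref <- growth_ref()
  r38 <- ref[ref$sex == "female" & ref$gestational_week == 38, ]
  r39 <- ref[ref$sex == "female" & ref$gestational_week == 39, ]
  mu <- (r38$mean_g + r39$mean_g) / 2
  sd <- (r38$sd_g + r39$sd_g) / 2
  d <- tibble::tibble(individual_id = "a", sex = "female",
                      gestational_age_weeks = 38.5, birthweight_g = 3000)
  expect_equal(birthweight_z(d, ref)$birthweight_z, (3000 - mu) / sd)
})

test_that("gestational ages outside the reference range are an error", {
  ref <- growth_ref()
  d <- tibble::tibble(individual_id = "a", sex = "male",
                      gestational_age_weeks = 28, birthweight_g = 1200)
  expect_error(birthweight_z(d, ref), "outside the reference range")
})

test_that("z-score affine equivariance", {
  ref <- growth_ref()
  d <- tibble::tibble(individual_id = "a", sex = "male",
                      gestational_age_weeks = 40, birthweight_g = 3100)
  z0 <- birthweight_z(d, ref)$birthweight_z
  shifted <- dplyr::mutate(ref, mean_g = .data$mean_g + 250)
  d2 <- dplyr::mutate(d, birthweight_g = .data$birthweight_g + 250)
  expect_equal(birthweight_z(d2, shifted)$birthweight_z, z0)
  scaled <- dplyr::mutate(ref, sd_g = 2 * .data$sd_g)
  expect_equal(birthweight_z(d, scaled)$birthweight_z, z0 / 2)
})

test_that("reference validation flags bad tables", {
  ref <- growth_ref()
  expect_error(validate_growth_reference(dplyr::mutate(ref, sd_g = 0)), "positive")
  dec <- ref
  dec$mean_g[3] <- dec$mean_g[2] - 100
  expect_warning(validate_growth_reference(dec), "not strictly increasing")
})

test_that("regression handles exact, constant, and hand-oracle cases", {
  lin <- tibble::tibble(age_at_diagnosis_weeks = 0:5,
                        birthweight_z = 2 * (0:5) + 1)
  f <- suppressWarnings(regress_z_on_age(lin))  # lm warns on an exact fit
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)

  const <- tibble::tibble(age_at_diagnosis_weeks = c(0, 1, 2, 3),
                          birthweight_z = rep(1.5, 4))
  fc <- suppressWarnings(regress_z_on_age(const))
  expect_equal(fc$slope, 0)
  expect_equal(fc$r_squared, 0)

  tri <- tibble::tibble(age_at_diagnosis_weeks = c(0, 1, 2),
                        birthweight_z = c(0, 1, 0))
  ft <- regress_z_on_age(tri)
  o <- oracle_ols(c(0, 1, 2), c(0, 1, 0))
  expect_equal(ft$slope, o$slope)
  expect_equal(ft$intercept, o$intercept)   # 1/3 by the normal equations
  expect_equal(ft$intercept, 1 / 3)
  expect_equal(ft$r_squared, o$r_squared)

  expect_error(regress_z_on_age(lin[1:2, ]), "at least 3")
  degen <- tibble::tibble(age_at_diagnosis_weeks = rep(2, 4),
                          birthweight_z = rnorm(4))
  expect_error(regress_z_on_age(degen), "degenerate")
})

test_that("r-squared is invariant to affine rescaling of x and y", {
  d <- withr::with_seed(13, tibble::tibble(
    age_at_diagnosis_weeks = runif(30, 1, 26),
    birthweight_z = -1.5 + 0.05 * runif(30, 1, 26) + rnorm(30, 0, 0.5)))
  f1 <- regress_z_on_age(d)
  d2 <- dplyr::mutate(d, age_at_diagnosis_weeks = 7 * .data$age_at_diagnosis_weeks - 3,
                      birthweight_z = -2 * .data$birthweight_z + 5)
  f2 <- regress_z_on_age(d2)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-9)
})

test_that("tidy/glance expose slope, r-squared and p", {
  d <- withr::with_seed(2, tibble::tibble(
    age_at_diagnosis_weeks = runif(20, 1, 26),
    birthweight_z = rnorm(20)))
  f <- regress_z_on_age(d)
  expect_equal(tidy(f)$estimate[2], f$slope)
  g <- glance(f)
  expect_true(g$r_squared >= 0 && g$r_squared <= 1)
  expect_equal(g$n, 20L)
})
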