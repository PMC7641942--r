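# small long-format antibody fixture builder
ab_rows <- function(group, n, n_pos, analyte = "GADA", cutoff = 10,
                    prefix = group, duration = NULL) {
  tibble::tibble(
    individual_id = paste0(prefix, seq_len(n)), group = group,
    analyte = analyte,
    titre = c(rep(2 * cutoff, n_pos), rep(cutoff / 2, n - n_pos)),
    cutoff = cutoff,
    insulin_duration_weeks = if (is.null(duration)) NA_real_ else duration
  )
}

test_that("positivity is strict at the cut-off", {
  expect_false(call_positive(10, 10))
  expect_true(call_positive(20, 10))
  expect_error(call_positive(-1, 10), "non-negative")
  expect_error(call_positive(1, 0), "positive")
})

test_that("panel summary reproduces the 9/22 any-positive proportion", {
  calls <- dplyr::bind_rows(
    ab_rows("unknown_high_GRS", 22, 6, "GADA"),
    ab_rows("unknown_high_GRS", 22, 4, "IA2A"),
    ab_rows("unknown_high_GRS", 22, 3, "ZnT8A")
  )
  # overlap the positives so exactly 9 individuals carry >= 1 positive call:
  # GADA positives are ids 1-6, IA2A on 1,2,7,8 and ZnT8A on 1,3,9
  calls$titre[calls$analyte == "IA2A"] <- 5
  calls$titre[calls$analyte == "IA2A"][c(1, 2, 7, 8)] <- 20
  calls$titre[calls$analyte == "ZnT8A"] <- 5
  calls$titre[calls$analyte == "ZnT8A"][c(1, 3, 9)] <- 20
  ps <- summarize_panel(calls)
  expect_equal(ps$n_measured, 22L)
  expect_equal(ps$n_any_positive, 9L)
  expect_equal(proportion_report(ps$n_any_positive, ps$n_measured), "9/22 (41%)")
  expect_equal(ps$n_two_positive, 3L)   # ids 1, 2, 3
  expect_equal(ps$n_three_positive, 1L) # id 1
  expect_equal(ps$GADA_pos, 6L)
  expect_true(ps$n_three_positive <= ps$n_two_positive &&
                ps$n_two_positive <= ps$n_any_positive &&
                ps$n_any_positive <= ps$n_measured)
})

test_that("panel counts equal a brute-force recount on a randomised fixture", {
  calls <- withr::with_seed(21, {
    n <- 40
    dplyr::bind_rows(lapply(c("GADA", "IA2A", "ZnT8A"), function(a) {
      keep <- runif(n) < 0.8   # not everyone measured for every analyte
      tibble::tibble(individual_id = paste0("i", seq_len(n)),
                     group = rep(c("g1", "g2"), each = n / 2),
                     analyte = a, titre = rlnorm(n, 2, 1), cutoff = 8)[keep, ]
    }))
  })
  ps <- summarize_panel(calls)
  for (g in c("g1", "g2")) {
    sub <- calls[calls$group == g, ]
    pos_by_ind <- tapply(sub$titre > sub$cutoff, sub$individual_id, sum)
    row <- ps[ps$group == g, ]
    expect_equal(row$n_measured, length(pos_by_ind))
    expect_equal(row$n_any_positive, sum(pos_by_ind >= 1))
    expect_equal(row$n_two_positive, sum(pos_by_ind >= 2))
    expect_equal(row$n_three_positive, sum(pos_by_ind >= 3))
  }
  expect_error(summarize_panel(dplyr::bind_rows(calls, calls[1, ])), "duplicate")
})

test_that("panel monotonicity: adding a positive, removing an individual", {
  calls <- ab_rows("g", 10, 2)
  base <- summarize_panel(calls)
  more <- dplyr::bind_rows(calls, ab_rows("g", 1, 1, "IA2A", prefix = "new"))
  expect_gte(summarize_panel(more)$n_any_positive, base$n_any_positive)
  fewer <- summarize_panel(calls[calls$individual_id != "g1", ])
  expect_equal(fewer$n_measured, base$n_measured - 1L)
})

test_that("IAA duration strata reproduce the short-duration comparison", {
  calls <- dplyr::bind_rows(
    ab_rows("unknown_high_GRS", 8, 4, "IAA", duration = 10),
    ab_rows("monogenic_NDM", 75, 6, "IAA", duration = 13)  # boundary is inclusive
  )
  s <- iaa_duration_summary(calls)
  expect_equal(s$stratum, c("short", "short"))
  high <- s[s$group == "unknown_high_GRS", ]
  mono <- s[s$group == "monogenic_NDM", ]
  expect_equal(high$proportion, 0.5)
  expect_equal(mono$proportion, 6 / 75, tolerance = 1e-12)
  expect_equal(round(fisher_exact(4, 4, 6, 69)$p, 3), 0.006)

  # missing durations are excluded with a warning
  calls$insulin_duration_weeks[1] <- NA
  expect_warning(s2 <- iaa_duration_summary(calls), "excluding 1")
  expect_equal(sum(s2$n), 82L)
})

test_that("C-peptide LOD coding is correct and idempotent", {
  expect_equal(code_cpeptide(1.2), 2.9)
  expect_equal(code_cpeptide(3.0), 3.0)
  expect_equal(code_cpeptide(250.0), 250.0)
  expect_equal(code_cpeptide("<3"), 2.9)
  expect_equal(code_cpeptide(c("<3", "7.5", NA)), c(2.9, 7.5, NA))
  x <- c(0.4, 2.9, 3, 17)
  expect_equal(code_cpeptide(code_cpeptide(x)), code_cpeptide(x))
  expect_error(code_cpeptide(-1), "non-negative")
})

test_that("C-peptide group summary reproduces the 14/19 undetectable fraction", {
  d <- tibble::tibble(
    group = "unknown_high_GRS",
    cpeptide_pmol_l = c(rep("<3", 14), "10", "25", "38", "5", "12"),
    diabetes_duration_months = 24
  )
  s <- cpeptide_group_summary(d)
  expect_equal(s$n, 19L)
  expect_equal(s$n_undetectable, 14L)
  expect_equal(proportion_report(s$n_undetectable, s$n), "14/19 (74%)")
  expect_equal(s$median, 2.9)

  # constant values and the sort-based median/IQR oracle
  dc <- tibble::tibble(group = "g", cpeptide_pmol_l = rep(100, 5),
                       diabetes_duration_months = 3)
  sc <- cpeptide_group_summary(dc)
  expect_equal(c(sc$median, sc$q25, sc$q75, sc$undetectable_fraction),
               c(100, 100, 100, 0))
  vals <- withr::with_seed(8, rlnorm(31, 3, 1))
  dr <- tibble::tibble(group = "g", cpeptide_pmol_l = vals,
                       diabetes_duration_months = 20)
  sr <- cpeptide_group_summary(dr)
  coded <- ifelse(vals < 3, 2.9, vals)
  expect_equal(sr$median, oracle_quantile(coded, 0.5))
  expect_equal(sr$q25, oracle_quantile(coded, 0.25))
  expect_equal(sr$q75, oracle_quantile(coded, 0.75))
})

test_that("duration boundary splits strata at 12 months", {
  d <- tibble::tibble(group = "g", cpeptide_pmol_l = c("5", "5", "5"),
                      diabetes_duration_months = c(3, 11.9, 12))
  s <- cpeptide_group_summary(d)
  expect_equal(s$n[s$stratum == "under_boundary"], 2L)
  expect_equal(s$n[s$stratum == "over_boundary"], 1L)
})
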