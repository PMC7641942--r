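#' Simulate a full synthetic referral cohort
#'
#' Generates, under a fixed seed, everything the pipeline consumes:
#'
#' * `genotypes.vcf` — GT-only VCF v4.2 of the referral cohort, ALT set to
#'   the effect allele so the written file round-trips exactly through
#'   [dosages_from_vcf()];
#' * `phenotypes.csv` — one row per individual (referral cohort plus the
#'   optional comparator groups), with antibody titres and cut-offs,
#'   C-peptide (`"<3"` below the limit of detection), birthweight,
#'   gestational age, sex, ages and durations;
#' * `reference_scores.csv` — genetic risk scores of the simulated control
#'   reference panel;
#' * `truth.csv` — the withheld class labels, for evaluation only;
#' * `config.yml` — an echo of the scalar configuration.
#'
#' `round(pi * n_cohort)` individuals are polygenic cases (odds-ratio-tilted
#' genotypes) and the remainder monogenic-like (control genotypes); the two
#' classes are interleaved deterministically by a seeded shuffle.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory, created if needed. `NULL` (default)
#'   skips writing and returns the tables only.
#' @return Invisibly, a list with `genotypes`, `phenotypes`, `truth`,
#'   `reference_scores` tibbles and, if written, `paths`.
#' @export
simulate_cohort <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config, outdir))
}

simulate_cohort_impl <- function(config, outdir) {
  n_poly <- as.integer(round(config$pi * config$n_cohort))
  n_mono <- config$n_cohort - n_poly

  geno_poly <- if (n_poly > 0) simulate_case_genotypes(config, n_poly) else NULL
  geno_mono <- if (n_mono > 0) simulate_control_genotypes(config, n_mono) else NULL
  classes <- c(rep("polygenic", n_poly), rep("monogenic", n_mono))
  geno <- dplyr::bind_rows(geno_poly, geno_mono)
  ord <- sample.int(nrow(geno))
  geno <- geno[ord, , drop = FALSE]
  classes <- classes[ord]
  geno$individual_id <- sprintf("U%04d", seq_len(nrow(geno)))

  ref_geno <- simulate_control_genotypes(config, config$n_reference, "R")
  ref_scores <- compute_grs(ref_geno, config$weights)

  growth_ref <- shipped_growth_reference()
  pheno_cohort <- simulate_phenotypes(config, geno$individual_id, classes,
                                      "unknown", growth_ref)
  pheno_extra <- list()
  if (config$n_monogenic_comparator > 0) {
    ids <- sprintf("M%04d", seq_len(config$n_monogenic_comparator))
    pheno_extra$mono <- simulate_phenotypes(
      config, ids, rep("monogenic", length(ids)), "monogenic_NDM", growth_ref)
  }
  if (config$n_t1d_comparator > 0) {
    ids <- sprintf("T%04d", seq_len(config$n_t1d_comparator))
    pheno_extra$t1d <- simulate_phenotypes(
      config, ids, rep("t1d_6_24m", length(ids)), "T1D_6_24m", growth_ref)
  }
  phenotypes <- dplyr::bind_rows(c(list(pheno_cohort), unname(pheno_extra)))
  truth <- tibble::tibble(individual_id = geno$individual_id, true_class = classes)

  out <- list(genotypes = geno, phenotypes = phenotypes, truth = truth,
              reference_scores = ref_scores)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      vcf = file.path(outdir, "genotypes.vcf"),
      phenotypes = file.path(outdir, "phenotypes.csv"),
      reference_scores = file.path(outdir, "reference_scores.csv"),
      truth = file.path(outdir, "truth.csv"),
      config = file.path(outdir, "config.yml")
    )
    write_dosage_vcf(geno, config$weights, paths$vcf)
    readr::write_csv(phenotypes, paths$phenotypes)
    readr::write_csv(ref_scores["grs"], paths$reference_scores)
    readr::write_csv(truth, paths$truth)
    yaml::write_yaml(list(
      m = config$m, n_reference = config$n_reference,
      n_cohort = config$n_cohort, pi = config$pi,
      n_monogenic_comparator = config$n_monogenic_comparator,
      n_t1d_comparator = config$n_t1d_comparator, seed = config$seed
    ), paths$config)
    out$paths <- paths
  }
  invisible(out)
}

# phenotype block for one set of individuals of known classes
simulate_phenotypes <- function(config, ids, classes, group, growth_ref) {
  n <- length(ids)
  am <- config$antibody_model
  cm <- config$cpeptide_model
  bm <- config$birthweight_model
  agem <- config$age_model

  age <- numeric(n)
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    pars <- agem[[cl]]
    if (cl == "t1d_6_24m") {
      age[idx] <- runif(length(idx), pars[["min_weeks"]], pars[["max_weeks"]])
    } else {
      age[idx] <- pmax(0.1, rbeta(length(idx), pars[["shape1"]], pars[["shape2"]]) *
                         pars[["max_weeks"]])
    }
  }
  age <- round(age, 1)

  sex <- ifelse(runif(n) < 0.42, "female", "male")
  ga <- round(pmin(42, pmax(32, rnorm(n, 39, 1.5))), 1)

  z <- numeric(n)
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    p <- bm[[cl]]
    z[idx] <- rnorm(length(idx), p[["mu0"]] + p[["beta"]] * age[idx], p[["sigma"]])
  }
  bw <- round(birthweight_from_z(z, sex, ga, growth_ref))

  # diabetes duration at sampling; insulin is given from diagnosis
  dur_m <- round(rlnorm(n, log(8), 1.5), 1)
  dur_w <- round(dur_m * 4.345, 1)

  pheno <- tibble::tibble(
    individual_id = ids, group = group, sex = sex,
    age_at_diagnosis_weeks = age,
    gestational_age_weeks = ga, birthweight_g = bw,
    insulin_duration_weeks = dur_w, diabetes_duration_months = dur_m
  )

  for (analyte in names(am$cutoffs)) {
    cutoff <- am$cutoffs[[analyte]]
    pos_p <- vapply(classes, function(cl) am$positivity[[cl]][[analyte]], 0)
    is_pos <- runif(n) < pos_p
    neg_meanlog <- log(cutoff) - qnorm(0.99) * am$neg_sdlog
    titre <- rlnorm(n, neg_meanlog, am$neg_sdlog)
    if (any(is_pos)) {
      titre[is_pos] <- cutoff *
        (1 + rlnorm(sum(is_pos), am$pos_meanlog, am$pos_sdlog))
    }
    pheno[[paste0(analyte, "_titre")]] <- round(titre, 2)
    pheno[[paste0(analyte, "_cutoff")]] <- cutoff
  }

  cpep <- numeric(n)
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    p <- cm[[cl]]
    cpep[idx] <- rlnorm(length(idx), p[["meanlog"]], p[["sdlog"]])
  }
  pheno$cpeptide_pmol_l <- ifelse(cpep < cm$lod, paste0("<", cm$lod),
                                  as.character(round(cpep, 1)))
  pheno
}

# growth reference shipped with the package (synthetic values)
shipped_growth_reference <- function() {
  read_growth_reference(system.file("extdata", "synthetic_growth_reference.csv",
                                    package = "earlyt1d", mustWork = TRUE))
}

#' Write a dosage table as a GT-only VCF
#'
#' Sites are written with REF = other allele and ALT = effect allele, so the
#' ALT-allele count equals the effect-allele dosage. Synthetic positions are
#' assigned deterministically.
#'
#' @param dosages Wide dosage tibble (no missing values).
#' @param weights Weight table supplying the alleles.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dosage_vcf <- function(dosages, weights, path) {
  snps <- weights$snp_id
  gt_codes <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=earlyt1d simulate_cohort (synthetic data)",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", dosages$individual_id), collapse = "\t")
  )
  body <- vapply(seq_along(snps), function(i) {
    d <- dosages[[snps[i]]]
    if (any(is.na(d))) abort("write_dosage_vcf does not support missing dosages")
    paste(c(((i - 1) %% 22) + 1, i * 1000000, snps[i],
            weights$other_allele[i], weights$effect_allele[i],
            ".", "PASS", ".", "GT", gt_codes[d + 1]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
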