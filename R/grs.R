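#' Compute the type 1 diabetes genetic risk score
#'
#' For each individual, sums the log10 odds-ratio weights over the copies of
#' each effect allele carried and divides by the total number of alleles
#' counted (twice the number of non-missing SNPs), giving a per-allele mean
#' weight.
#'
#' Missing genotypes are handled by `missing_policy`:
#' * `"reduce-denominator"` (default): missing SNPs are dropped from both the
#'   numerator and the denominator, so the score stays a per-allele mean and
#'   remains comparable across missingness patterns.
#' * `"drop-individual"`: individuals with more than `max_missing` missing
#'   SNPs are removed (a message reports how many); the rest are scored with
#'   the reduced denominator.
#'
#' @param dosages Wide dosage tibble from [dosages_from_vcf()] or the
#'   simulators: `individual_id` plus one 0/1/2/NA column per SNP.
#' @param weights Weight table; every dosage SNP must appear in it.
#' @param missing_policy `"reduce-denominator"` or `"drop-individual"`.
#' @param max_missing Maximum missing SNPs tolerated under
#'   `"drop-individual"` (default 0).
#' @return A tibble with columns `individual_id`, `grs`, `n_snps_used`,
#'   `n_alleles`, `missing_count`, one row per scored individual, input order
#'   preserved.
#' @examples
#' w <- weight_table("rs1", "A", "G", 10)
#' d <- tibble::tibble(individual_id = c("s1", "s2"), rs1 = c(2L, 0L))
#' compute_grs(d, w)
#' @export
compute_grs <- function(dosages, weights,
                        missing_policy = c("reduce-denominator", "drop-individual"),
                        max_missing = 0L) {
  missing_policy <- match.arg(missing_policy)
  snp_cols <- setdiff(names(dosages), "individual_id")
  unknown <- setdiff(snp_cols, weights$snp_id)
  if (length(unknown) > 0) {
    abort(paste0("dosage SNP(s) absent from the weight table: ",
                 paste(unknown, collapse = ", ")))
  }
  m <- length(snp_cols)
  dmat <- as.matrix(dosages[, snp_cols, drop = FALSE])
  storage.mode(dmat) <- "double"
  if (any(!is.na(dmat) & (dmat < 0 | dmat > 2 | dmat != round(dmat)))) {
    abort("dosages must be integers in 0..2 or missing")
  }
  w <- weights$weight[match(snp_cols, weights$snp_id)]

  present <- !is.na(dmat)
  n_used <- rowSums(present)
  if (any(n_used == 0)) {
    abort(paste0("individual(s) with no non-missing SNPs (score undefined): ",
                 paste(dosages$individual_id[n_used == 0], collapse = ", ")))
  }
  dmat0 <- dmat
  dmat0[!present] <- 0
  numerator <- as.vector(dmat0 %*% w)
  scores <- tibble::tibble(
    individual_id = dosages$individual_id,
    grs = numerator / (2 * n_used),
    n_snps_used = as.integer(n_used),
    n_alleles = as.integer(2 * n_used),
    missing_count = as.integer(m - n_used)
  )
  if (missing_policy == "drop-individual") {
    dropped <- scores$missing_count > max_missing
    if (any(dropped)) {
      inform(paste0("dropping ", sum(dropped), " individual(s) with more than ",
                    max_missing, " missing SNPs: ",
                    paste(scores$individual_id[dropped], collapse = ", ")))
      scores <- scores[!dropped, , drop = FALSE]
    }
  }
  scores
}

#' Classify scores as high or low against a threshold
#'
#' Labels each individual `"high"` if the score strictly exceeds the
#' threshold, `"low"` otherwise; a score exactly at the threshold is low.
#' The study threshold for the T1D-GRS is 0.280, the 95th centile of a
#' control population without type 1 diabetes.
#'
#' @param scores Tibble with columns `individual_id` and `grs`
#'   (as returned by [compute_grs()]).
#' @param threshold Finite numeric cut-point on the score scale.
#' @return The input tibble with an added character column
#'   `label` in `{"high","low"}`; row order preserved.
#' @export
classify_high_low <- function(scores, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 || !is.finite(threshold)) {
    abort("threshold must be a single finite number")
  }
  dplyr::mutate(scores, label = ifelse(.data$grs > threshold, "high", "low"))
}
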