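#' Read a SNP weight table
#'
#' Reads the tab-separated table of risk SNPs defining a genetic risk score.
#' Each row names a SNP, its effect (risk) allele, the other allele, and the
#' per-allele odds ratio for type 1 diabetes. The score weight is the
#' log10-transformed odds ratio.
#'
#' @param path Path to a TSV file with header columns `snp_id`,
#'   `effect_allele`, `other_allele`, `odds_ratio`.
#' @return A tibble with the four input columns plus `weight = log10(odds_ratio)`,
#'   in file row order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("snp_id\teffect_allele\tother_allele\todds_ratio",
#'              "rs1\tA\tG\t10.0"), tf)
#' read_weight_table(tf)
#' @export
read_weight_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    snp_id = readr::col_character(),
    effect_allele = readr::col_character(),
    other_allele = readr::col_character(),
    odds_ratio = readr::col_character()
  ))
  required <- c("snp_id", "effect_allele", "other_allele", "odds_ratio")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("weight table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  or_num <- suppressWarnings(as.numeric(tbl$odds_ratio))
  bad <- which(is.na(or_num) | !is.finite(or_num) | or_num <= 0)
  if (length(bad) > 0) {
    abort(paste0("odds_ratio must be a positive finite number; offending row(s): ",
                 paste(bad, collapse = ", ")))
  }
  tbl$odds_ratio <- or_num
  validate_weight_table(
    dplyr::mutate(tbl, weight = log10(.data$odds_ratio))
  )
}

#' Construct a weight table from vectors
#'
#' Programmatic counterpart of [read_weight_table()], used mainly by the
#' synthetic-cohort generator.
#'
#' @param snp_id,effect_allele,other_allele,odds_ratio Parallel vectors, one
#'   entry per SNP.
#' @return A validated weight-table tibble with a `weight` column.
#' @export
weight_table <- function(snp_id, effect_allele, other_allele, odds_ratio) {
  validate_weight_table(tibble::tibble(
    snp_id = as.character(snp_id),
    effect_allele = as.character(effect_allele),
    other_allele = as.character(other_allele),
    odds_ratio = as.numeric(odds_ratio),
    weight = log10(as.numeric(odds_ratio))
  ))
}

validate_weight_table <- function(tbl) {
  dup <- tbl$snp_id[duplicated(tbl$snp_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate snp_id in weight table: ",
                 paste(unique(dup), collapse = ", ")))
  }
  bases <- c("A", "C", "G", "T")
  bad_allele <- !(tbl$effect_allele %in% bases) | !(tbl$other_allele %in% bases)
  if (any(bad_allele)) {
    abort(paste0("malformed allele (must be a single base A/C/G/T) in row(s): ",
                 paste(which(bad_allele), collapse = ", ")))
  }
  same <- tbl$effect_allele == tbl$other_allele
  if (any(same)) {
    abort(paste0("effect_allele equals other_allele in row(s): ",
                 paste(which(same), collapse = ", ")))
  }
  if (any(!is.finite(tbl$odds_ratio) | tbl$odds_ratio <= 0)) {
    abort("odds_ratio must be positive and finite")
  }
  if (nrow(tbl) < 1) abort("weight table must have at least one SNP")
  tbl
}

# strand-ambiguous SNPs cannot be resolved by complementing
is_strand_ambiguous <- function(a1, a2) {
  paste0(a1, a2) %in% c("AT", "TA", "CG", "GC")
}

complement_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[b])
}
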