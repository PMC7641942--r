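#' Extract effect-allele dosages from a VCF
#'
#' Reads genotypes (GT only) from a VCF and converts them to effect-allele
#' dosages (0, 1, 2 or missing) for the SNPs of a weight table. Sites are
#' matched by the VCF ID column. When the VCF's ALT allele is the effect
#' allele the dosage is the ALT-allele count; when REF is the effect allele
#' it is `2 - ALT count`.
#'
#' Under `strand_policy = "flip-unambiguous"` a site whose alleles match the
#' weight table only after base complementing is accepted, unless the SNP is
#' strand-ambiguous (A/T or C/G), which is always an error rather than a
#' silent flip. Under `"strict"` any allele mismatch is an error.
#'
#' @param vcf_path Path to a VCF (v4.x) file; may be bgzipped.
#' @param weights A weight table from [read_weight_table()].
#' @param strand_policy `"strict"` (default) or `"flip-unambiguous"`.
#' @return A wide tibble: `individual_id` plus one integer column per
#'   weight-table SNP (in weight-table order), `NA` where the genotype is
#'   uncalled or the SNP is absent from the VCF.
#' @export
dosages_from_vcf <- function(vcf_path, weights,
                             strand_policy = c("strict", "flip-unambiguous")) {
  strand_policy <- match.arg(strand_policy)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) abort("VCF has no GT field")
  individuals <- colnames(gt)

  out <- tibble::tibble(individual_id = individuals)
  for (i in seq_len(nrow(weights))) {
    snp <- weights$snp_id[i]
    ea <- weights$effect_allele[i]
    oa <- weights$other_allele[i]
    row <- which(fix[, "ID"] == snp)
    if (length(row) == 0) {
      out[[snp]] <- NA_integer_
      next
    }
    if (length(row) > 1) abort(paste0("SNP ", snp, " appears more than once in the VCF"))
    ref <- fix[row, "REF"]
    alt <- fix[row, "ALT"]
    if (grepl(",", alt, fixed = TRUE)) {
      abort(paste0("multiallelic site at scored SNP ", snp))
    }
    orientation <- match_alleles(snp, ref, alt, ea, oa, strand_policy)
    alt_count <- count_alt_alleles(gt[row, , drop = TRUE])
    dosage <- if (orientation == "alt_is_effect") alt_count else 2L - alt_count
    out[[snp]] <- dosage
  }
  out
}

# decide whether ALT or REF carries the effect allele, honouring the strand policy
match_alleles <- function(snp, ref, alt, ea, oa, strand_policy) {
  if (alt == ea && ref == oa) return("alt_is_effect")
  if (ref == ea && alt == oa) return("ref_is_effect")
  if (strand_policy == "flip-unambiguous") {
    if (is_strand_ambiguous(ea, oa)) {
      abort(paste0("SNP ", snp, " is strand-ambiguous (", ea, "/", oa,
                   ") and does not match the VCF alleles directly; refusing to flip"))
    }
    cref <- complement_base(ref)
    calt <- complement_base(alt)
    if (calt == ea && cref == oa) return("alt_is_effect")
    if (cref == ea && calt == oa) return("ref_is_effect")
  }
  abort(paste0("allele mismatch at SNP ", snp, ": VCF ", ref, "/", alt,
               " vs weight table ", ea, "/", oa))
}

count_alt_alleles <- function(gt_strings) {
  vapply(gt_strings, function(g) {
    if (is.na(g)) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles == "1")
  }, integer(1), USE.NAMES = FALSE)
}
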