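# Biallelic deletion genotypes are one of four states.
GT_STATES <- c("REF_REF", "REF_DEL", "DEL_DEL", "MISSING")

# Parse VCF GT strings into genotype states. Phasing separators are
# normalised; any allele index above 1 yields NA so the caller can reject
# the record (the analysis is strictly biallelic).
parse_gt <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep(NA_character_, length(gt))
  out[gt %in% c(".", "./.", "")] <- "MISSING"
  out[gt %in% c("0/0")] <- "REF_REF"
  out[gt %in% c("0/1", "1/0")] <- "REF_DEL"
  out[gt %in% c("1/1")] <- "DEL_DEL"
  out[gt %in% c("./0", "0/.")] <- "REF_REF"
  out[gt %in% c("./1", "1/.")] <- "REF_DEL"
  out
}

format_gt <- function(state) {
  c(REF_REF = "0/0", REF_DEL = "0/1", DEL_DEL = "1/1", MISSING = "./.")[state]
}

#' Allelic state of a deletion genotype
#'
#' Collapses genotype states to the allelic state reported in per-sample
#' tabulations: heterozygous, homozygous for the deletion, or no deleted
#' allele. Missing genotypes contribute to no allele counts.
#'
#' @param genotype Character vector of genotype states (`"REF_REF"`,
#'   `"REF_DEL"`, `"DEL_DEL"`, `"MISSING"`).
#' @return Character vector with values `"HET"`, `"HOM"`, `"NONE"`.
#' @examples
#' allele_state(c("REF_DEL", "DEL_DEL", "REF_REF", "MISSING"))
#' @export
allele_state <- function(genotype) {
  bad <- !genotype %in% GT_STATES
  if (any(bad)) ds_stop("unknown genotype state: ", genotype[which(bad)[1]])
  c(REF_REF = "NONE", REF_DEL = "HET", DEL_DEL = "HOM",
    MISSING = "NONE")[genotype]
}

# Number of deleted alleles carried by a genotype state (MISSING -> NA).
allele_dose <- function(genotype) {
  c(REF_REF = 0L, REF_DEL = 1L, DEL_DEL = 2L, MISSING = NA_integer_)[genotype]
}
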