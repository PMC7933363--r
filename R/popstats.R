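#' Per-sample deletion counts by allelic state
#'
#' Counts, for every sample in the cohort, its consensus deletions carrying
#' one deleted allele (`n_het`) or two (`n_hom`). Samples present in the
#' population map but without any consensus call get zero counts.
#'
#' @param consensus Consensus call table (rows from [intersect_callsets()],
#'   concatenated across samples), or any call table with `sample_id` and
#'   `genotype` columns.
#' @param sample_to_population Named character vector mapping sample to
#'   population; every sample appearing in `consensus` must be present.
#' @return `data.frame(sample_id, population, n_het, n_hom)`, one row per
#'   mapped sample, ordered by population then sample.
#' @export
per_sample_counts <- function(consensus, sample_to_population) {
  unknown <- setdiff(unique(consensus$sample_id), names(sample_to_population))
  if (length(unknown)) {
    ds_stop("sample(s) missing from population map: ",
            paste(unknown, collapse = ", "))
  }
  samples <- names(sample_to_population)
  state <- if (nrow(consensus)) allele_state(consensus$genotype) else character(0)
  sf <- factor(consensus$sample_id, levels = samples)
  out <- data.frame(
    sample_id = samples,
    population = unname(sample_to_population[samples]),
    n_het = as.integer(table(sf[state == "HET"])[samples]),
    n_hom = as.integer(table(sf[state == "HOM"])[samples]),
    stringsAsFactors = FALSE)
  out$n_het[is.na(out$n_het)] <- 0L
  out$n_hom[is.na(out$n_hom)] <- 0L
  out <- out[order(out$population, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Population summaries of per-sample deletion counts
#'
#' Mean and sample standard deviation (n - 1 denominator) of per-sample
#' heterozygous and homozygous deletion counts within each population.
#' Populations with a single sample report `NA` standard deviations.
#'
#' @param counts Output of [per_sample_counts()].
#' @return `data.frame(population, n_samples, mean_het, sd_het, mean_hom,
#'   sd_hom)`, ordered by population.
#' @export
population_summary <- function(counts) {
  pops <- sort(unique(counts$population))
  out <- do.call(rbind, lapply(pops, function(p) {
    x <- counts[counts$population == p, , drop = FALSE]
    data.frame(population = p, n_samples = nrow(x),
               mean_het = mean(x$n_het),
               sd_het = if (nrow(x) > 1L) sd(x$n_het) else NA_real_,
               mean_hom = mean(x$n_hom),
               sd_hom = if (nrow(x) > 1L) sd(x$n_hom) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Squared correlation of per-sample call counts between two callers
#'
#' Measures caller agreement as the squared Pearson correlation of the
#' number of deletion calls each caller made per sample (conventionally on
#' size-filtered raw calls, before the consensus intersection).
#'
#' @param counts_a,counts_b Data frames with `sample_id` and a count column
#'   `n` (or plain named numeric vectors), one entry per sample. Samples
#'   are paired by id.
#' @return Squared Pearson correlation, or `NA` (with a notice) when either
#'   vector has zero variance. At least three paired samples are required.
#' @export
caller_count_correlation <- function(counts_a, counts_b) {
  as_vec <- function(x) {
    if (is.data.frame(x)) setNames(x$n, x$sample_id) else x
  }
  a <- as_vec(counts_a); b <- as_vec(counts_b)
  common <- intersect(names(a), names(b))
  if (length(common) < 3L) ds_stop("need >= 3 paired samples")
  a <- a[common]; b <- b[common]
  if (sd(a) == 0 || sd(b) == 0) {
    ds_note("zero variance in per-sample counts; correlation undefined")
    return(NA_real_)
  }
  cor(a, b)^2
}

# Per-sample raw call counts for one caller (after size filtering), as used
# by caller_count_correlation.
raw_call_counts <- function(calls, samples) {
  tab <- table(factor(calls$sample_id, levels = samples))
  data.frame(sample_id = samples, n = as.integer(tab[samples]),
             stringsAsFactors = FALSE)
}
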