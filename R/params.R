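#' Pipeline parameters
#'
#' Bundles the tunable thresholds of the deletion-consensus pipeline. The
#' defaults are the analysis conditions used throughout the package: calls
#' supported by both callers at >= 50% reciprocal overlap, restricted to
#' deletions of 500 bp to 100 kb, a 1000 bp regulatory flank around
#' protein-coding genes, a strict > 5% allele-frequency gate for the gene
#' catalog, and a 0.05 significance level applied to BH-adjusted enrichment
#' q-values.
#'
#' @param ro_threshold Reciprocal-overlap fraction required to consider two
#'   deletion intervals the same event, in (0, 1]. The comparison is
#'   inclusive (`>=`).
#' @param min_len,max_len Inclusive size bounds (bp) for deletions kept in
#'   the analysis.
#' @param flank Regulatory flank (bp) extending up- and downstream of every
#'   protein-coding gene span.
#' @param af_threshold Allele-frequency gate for the gene catalog; loci enter
#'   the catalog only when their maximum per-population allele frequency is
#'   strictly greater than this fraction.
#' @param alpha Significance level applied to BH-adjusted q-values.
#' @param primary_caller Identifier of the caller whose coordinates and
#'   genotypes a consensus call carries.
#'
#' @return A list of class `"pipeline_params"`.
#' @examples
#' pipeline_params()
#' pipeline_params(ro_threshold = 0.8, primary_caller = "manta")
#' @export
pipeline_params <- function(ro_threshold = 0.5,
                            min_len = 500L,
                            max_len = 100000L,
                            flank = 1000L,
                            af_threshold = 0.05,
                            alpha = 0.05,
                            primary_caller = "manta") {
  if (!is.numeric(ro_threshold) || length(ro_threshold) != 1L ||
      ro_threshold <= 0 || ro_threshold > 1) {
    ds_stop("ro_threshold must be a single value in (0, 1]")
  }
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  if (is.na(min_len) || is.na(max_len) || min_len <= 0L || min_len > max_len) {
    ds_stop("size bounds must satisfy 0 < min_len <= max_len")
  }
  flank <- as.integer(flank)
  if (is.na(flank) || flank < 0L) ds_stop("flank must be >= 0")
  if (af_threshold < 0 || af_threshold >= 1) {
    ds_stop("af_threshold must be in [0, 1)")
  }
  if (alpha <= 0 || alpha >= 1) ds_stop("alpha must be in (0, 1)")
  if (!is.character(primary_caller) || length(primary_caller) != 1L ||
      !nzchar(primary_caller)) {
    ds_stop("primary_caller must be a non-empty string")
  }
  structure(
    list(ro_threshold = ro_threshold, min_len = min_len, max_len = max_len,
         flank = flank, af_threshold = af_threshold, alpha = alpha,
         primary_caller = primary_caller),
    class = "pipeline_params"
  )
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat("deletion pipeline parameters\n")
  cat(sprintf("  reciprocal overlap >= %g\n", x$ro_threshold))
  cat(sprintf("  size range         [%d, %d] bp\n", x$min_len, x$max_len))
  cat(sprintf("  regulatory flank   %d bp\n", x$flank))
  cat(sprintf("  catalog AF gate    > %g\n", x$af_threshold))
  cat(sprintf("  alpha (on q)       %g\n", x$alpha))
  cat(sprintf("  primary caller     %s\n", x$primary_caller))
  invisible(x)
}
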