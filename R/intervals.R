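# Genomic intervals are plain data frames with columns chrom (character),
# start, end (integers). Coordinates are 0-based half-open everywhere inside
# the package; conversion to and from 1-based conventions happens only in the
# format readers/writers (VCF, GFF3, alignment hits) and in the GRanges
# adaptors below.

#' Construct a genomic-interval table
#'
#' Builds and validates the 0-based half-open interval table used throughout
#' the package. Extra columns are carried along untouched.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; 0-based inclusive start, exclusive end.
#'   Every interval must satisfy `start >= 0` and `end > start`.
#' @param ... Further equal-length columns to attach (e.g. `sample_id`).
#'
#' @return A `data.frame` with at least columns `chrom`, `start`, `end`.
#' @examples
#' intervals(c("chr1", "chr2"), c(0, 999), c(500, 1500))
#' @export
intervals <- function(chrom, start, end, ...) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start),
                   end = as.integer(end),
                   ...,
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval") {
  if (!all(c("chrom", "start", "end") %in% names(df))) {
    ds_stop(what, " table must have columns chrom, start, end")
  }
  if (nrow(df) == 0L) return(invisible(df))
  if (anyNA(df$start) || anyNA(df$end) || anyNA(df$chrom)) {
    ds_stop(what, " table contains NA coordinates")
  }
  bad <- df$start < 0L | df$end <= df$start
  if (any(bad)) {
    ds_stop(sprintf("%d %s(s) violate start >= 0, end > start (first: %s:%d-%d)",
                    sum(bad), what, df$chrom[which(bad)[1]],
                    df$start[which(bad)[1]], df$end[which(bad)[1]]))
  }
  invisible(df)
}

interval_length <- function(df) df$end - df$start

# 0-based half-open data.frame -> 1-based closed GRanges (and back).
as_gr0 <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

gr_to_df0 <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

# Lower median: middle element for odd n, the smaller of the two middle
# elements for even n. Used for locus representative coordinates so that
# representatives are always observed breakpoints.
lower_median <- function(x) sort(x)[ceiling(length(x) / 2)]

#' Reciprocal overlap between paired intervals
#'
#' For each pair, the overlap in bases divided by the length of the longer
#' requirement: `min(overlap / length(a), overlap / length(b))`. Intervals on
#' different chromosomes have reciprocal overlap 0 by contract. The measure
#' is symmetric and lies in \[0, 1\].
#'
#' @param a,b Interval tables (see [intervals()]) of equal length, or with
#'   one of them a single row to be recycled.
#' @return Numeric vector of reciprocal-overlap fractions.
#' @examples
#' a <- intervals("chr1", 100, 200)
#' b <- intervals("chr1", 150, 250)
#' reciprocal_overlap(a, b)  # 0.5
#' @export
reciprocal_overlap <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  if (nrow(a) != nrow(b)) ds_stop("a and b must pair up row-wise")
  if (nrow(a) == 0L) return(numeric(0))
  ov <- pmax(0L, pmin(a$end, b$end) - pmax(a$start, b$start))
  ro <- pmin(ov / (a$end - a$start), ov / (b$end - b$start))
  ro[a$chrom != b$chrom] <- 0
  ro
}
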