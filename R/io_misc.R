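#' Read and write BED intervals
#'
#' Minimal 3+-column BED support. BED is already 0-based half-open, matching
#' the internal convention, so coordinates pass through unchanged.
#'
#' @param df Interval table with columns `chrom`, `start`, `end` and
#'   optionally `name`.
#' @param path File path.
#' @return `read_bed()` returns an interval `data.frame`; `write_bed()`
#'   returns `path` invisibly.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df)
  cols <- cbind(df$chrom, df$start, df$end,
                if (!is.null(df$name)) df$name)
  writeLines(apply(cols, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) ds_stop("BED not found: ", path)
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (ncol(raw) < 3L) ds_stop("BED needs >= 3 columns: ", path)
  df <- data.frame(chrom = as.character(raw[[1]]),
                   start = as.integer(raw[[2]]),
                   end = as.integer(raw[[3]]),
                   stringsAsFactors = FALSE)
  if (ncol(raw) >= 4L) df$name <- as.character(raw[[4]])
  validate_intervals(df)
  df
}

#' Read and write GMT gene-set files
#'
#' GMT is the tab-separated gene-set format: one set per line as
#' `name<TAB>description<TAB>member1<TAB>member2...`. Lines with fewer than
#' three fields are skipped with a warning. Written descriptions default to
#' `"na"`.
#'
#' @param path File path.
#' @param sets Named list of character vectors (set name -> member genes).
#' @return `read_gmt()` returns a named list of character vectors, with the
#'   descriptions attached as attribute `"description"`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) ds_stop("GMT not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3L
  if (any(short)) {
    warning(sprintf("%d GMT line(s) with < 3 fields skipped", sum(short)))
    fields <- fields[!short]
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  attr(sets, "description") <- setNames(
    vapply(fields, `[`, character(1), 2L), names(sets))
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  lines <- vapply(seq_along(sets), function(i) {
    d <- if (!is.null(desc) && names(sets)[i] %in% names(desc)) {
      desc[[names(sets)[i]]]
    } else "na"
    paste(c(names(sets)[i], d, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read 12-column tabular alignment hits
#'
#' Parses the standard 12-column tab-separated alignment-hit format
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`), the common tabular output of sequence search tools.
#' Subject coordinates are 1-based; `send < sstart` encodes a minus-strand
#' hit.
#'
#' @param path File path.
#' @return A `data.frame` with the twelve canonical columns, `marker_id`
#'   aliasing `qseqid`.
#' @export
read_hits_tsv <- function(path) {
  if (!file.exists(path)) ds_stop("hits TSV not found: ", path)
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (ncol(raw) < 12L) ds_stop("hits TSV needs 12 columns: ", path)
  names(raw)[1:12] <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                        "gapopen", "qstart", "qend", "sstart", "send",
                        "evalue", "bitscore")
  ev <- suppressWarnings(as.numeric(raw$evalue))
  if (anyNA(ev)) {
    ds_stop("non-numeric evalue at hits row ", which(is.na(ev))[1])
  }
  raw$evalue <- ev
  for (col in c("pident", "bitscore")) raw[[col]] <- as.numeric(raw[[col]])
  for (col in c("length", "mismatch", "gapopen", "qstart", "qend",
                "sstart", "send")) {
    raw[[col]] <- as.integer(raw[[col]])
  }
  if (any(raw$length < 1L)) ds_stop("alignment length < 1 in ", path)
  if (any(raw$evalue < 0)) ds_stop("negative evalue in ", path)
  raw$marker_id <- raw$qseqid
  raw
}

write_hits_tsv <- function(hits, path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  m <- hits[, cols]
  m$evalue <- format(m$evalue, trim = TRUE, scientific = TRUE, digits = 3)
  lines <- do.call(paste, c(lapply(m, as.character), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# Deterministic TSV writer used for all tabular artifacts.
write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
  })
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
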