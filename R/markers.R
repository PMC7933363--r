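#' Best placement for one marker from its alignment hits
#'
#' Selects the top hit by ranking e-value (ascending), then bitscore
#' (descending), then alignment length (descending). Residual ties after
#' all three keys are broken by lexicographically smallest `(sseqid,
#' sstart)` and flagged `ambiguous`, mirroring markers that cannot be
#' uniquely placed. The placement interval is normalised to 0-based
#' half-open with `start < end`; minus-strand hits (`send < sstart`) keep
#' strand `"-"` as metadata.
#'
#' @param hits `data.frame` of alignment hits for a single marker (see
#'   [read_hits_tsv()]).
#' @return One-row `data.frame(marker_id, chrom, start, end, strand,
#'   evalue, bitscore, length, ambiguous)`.
#' @export
top_hit <- function(hits) {
  if (nrow(hits) == 0L) ds_stop("top_hit needs >= 1 hit")
  if (length(unique(hits$marker_id)) > 1L) {
    ds_stop("top_hit received hits for several markers: ",
            paste(unique(hits$marker_id), collapse = ", "))
  }
  ord <- order(hits$evalue, -hits$bitscore, -hits$length,
               hits$sseqid, pmin(hits$sstart, hits$send))
  hits <- hits[ord, , drop = FALSE]
  key <- c(hits$evalue[1], hits$bitscore[1], hits$length[1])
  tied <- hits$evalue == key[1] & hits$bitscore == key[2] &
    hits$length == key[3]
  best <- hits[1L, ]
  data.frame(
    marker_id = best$marker_id,
    chrom = best$sseqid,
    start = min(best$sstart, best$send) - 1L,
    end = max(best$sstart, best$send),
    strand = if (best$send >= best$sstart) "+" else "-",
    evalue = best$evalue, bitscore = best$bitscore, length = best$length,
    ambiguous = sum(tied) > 1L,
    stringsAsFactors = FALSE)
}

#' Best placements for a whole hit table
#'
#' Applies [top_hit()] per marker.
#'
#' @param hits Alignment-hit table for any number of markers.
#' @return `data.frame` of placements, one row per marker, ordered by
#'   marker id.
#' @export
top_hits <- function(hits) {
  ids <- sort(unique(hits$marker_id))
  out <- do.call(rbind, lapply(ids, function(m) {
    top_hit(hits[hits$marker_id == m, , drop = FALSE])
  }))
  rownames(out) <- NULL
  out
}

#' Dual-genome marker mapping summary
#'
#' Partitions a marker universe by whether each marker obtained a placement
#' against each of two reference assemblies.
#'
#' @param placements_a,placements_b Placement tables (see [top_hits()]) or
#'   character vectors of mapped marker ids, one per assembly.
#' @param all_markers Character vector: the full marker universe.
#' @return Named integer vector with disjoint counts `both`, `a_only`,
#'   `b_only`, `neither`, summing to `length(all_markers)`.
#' @export
dual_genome_summary <- function(placements_a, placements_b, all_markers) {
  ids <- function(x) {
    if (is.data.frame(x)) unique(x$marker_id) else unique(as.character(x))
  }
  a <- ids(placements_a); b <- ids(placements_b)
  stray <- setdiff(union(a, b), all_markers)
  if (length(stray)) {
    ds_stop("placement for marker(s) outside the universe: ",
            paste(utils::head(stray, 3), collapse = ", "))
  }
  in_a <- all_markers %in% a
  in_b <- all_markers %in% b
  c(both = sum(in_a & in_b), a_only = sum(in_a & !in_b),
    b_only = sum(!in_a & in_b), neither = sum(!in_a & !in_b))
}

#' Genes overlapping an interval
#'
#' Returns every annotated gene whose span overlaps the query interval by
#' at least 1 bp, sorted by start — the candidate-gene lookup for a QTL
#' support interval anchored on the assembly.
#'
#' @param interval One-row interval table (or list with `chrom`, `start`,
#'   `end`), 0-based half-open.
#' @param annotation An `"sv_annotation"` object.
#' @param protein_coding_only Restrict to protein-coding genes (default
#'   `TRUE`).
#' @return Subset of the annotation's gene table.
#' @export
genes_in_interval <- function(interval, annotation,
                              protein_coding_only = TRUE) {
  q <- data.frame(chrom = as.character(interval$chrom[1]),
                  start = as.integer(interval$start[1]),
                  end = as.integer(interval$end[1]),
                  stringsAsFactors = FALSE)
  validate_intervals(q)
  genes <- if (protein_coding_only) pc_genes(annotation) else annotation$genes
  hit <- genes$chrom == q$chrom & genes$start < q$end & genes$end > q$start
  out <- genes[hit, , drop = FALSE]
  out <- out[order(out$start, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
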