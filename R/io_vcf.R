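#' Read deletion calls from a structural-variant VCF
#'
#' Parses a VCF 4.x file and returns only its deletion records as a call
#' table in internal 0-based half-open coordinates. Two record dialects are
#' supported:
#'
#' * symbolic records (`ALT = <DEL>`, or `INFO/SVTYPE = DEL` with a symbolic
#'   allele): the deleted span is `[POS, END)` in 0-based terms, since the
#'   1-based `POS` is the padding base preceding the deletion. When `END` is
#'   absent it is reconstructed from `|SVLEN|`; when both are present and
#'   disagree, `END` wins and a warning is tallied.
#' * explicit-allele records (`REF` longer than `ALT`): the deleted span
#'   starts after the shared padding base and has length
#'   `nchar(REF) - nchar(ALT)`.
#'
#' Non-deletion records (duplications, insertions, inversions, breakends)
#' are skipped and counted. Records that are multi-allelic, have `END <=
#' POS`, or carry a genotype allele index above 1 are rejected and counted.
#' Genotypes are taken from `FORMAT/GT` (phased separators normalised);
#' a missing GT yields state `"MISSING"`. Rows with genotype `0/0` are
#' dropped (the caller asserts no deletion for that sample), as are `./.`
#' rows in multi-sample files.
#'
#' @param path Path to a VCF file.
#' @param caller_id Identifier recorded in the `caller_id` column.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `sample_id`,
#'   `caller_id`, `genotype`, `qual`, `record_id`. Skip/reject counts are
#'   attached as attribute `"tally"` and reported via [message()].
#' @seealso [write_consensus_vcf()] for the inverse operation on consensus
#'   calls and loci.
#' @export
read_deletions_vcf <- function(path, caller_id) {
  if (!file.exists(path)) ds_stop("VCF not found: ", path)
  if (!is.character(caller_id) || !nzchar(caller_id)) {
    ds_stop("caller_id must be a non-empty string")
  }
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown"))
  n <- length(vcf)
  tally <- c(non_del = 0L, multiallelic = 0L, bad_coord = 0L, bad_gt = 0L,
             end_svlen_conflict = 0L)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      sample_id = character(), caller_id = character(),
                      genotype = character(), qual = numeric(),
                      record_id = character(), stringsAsFactors = FALSE)
  if (n == 0L) {
    attr(empty, "tally") <- tally
    return(empty)
  }

  rr <- SummarizedExperiment::rowRanges(vcf)
  pos1 <- GenomicRanges::start(rr)                  # 1-based POS
  chrom <- as.character(GenomicRanges::seqnames(rr))
  refs <- as.character(VariantAnnotation::ref(vcf))
  alt_l <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_l)
  alts <- rep(NA_character_, n)
  alts[n_alt == 1L] <- vapply(as.list(alt_l[n_alt == 1L]),
                              function(a) as.character(a)[1], character(1))
  inf <- VariantAnnotation::info(vcf)
  getcol <- function(name) {
    if (name %in% names(inf)) inf[[name]] else rep(NA, n)
  }
  svtype <- as.character(getcol("SVTYPE"))
  iend <- suppressWarnings(as.integer(getcol("END")))
  svlen <- suppressWarnings(as.integer(getcol("SVLEN")))
  quals <- VariantAnnotation::qual(vcf)
  ids <- names(rr)
  if (is.null(ids)) ids <- paste0(caller_id, ":", seq_len(n))

  geno_names <- tryCatch(rownames(VariantAnnotation::geno(
    VariantAnnotation::header(vcf))), error = function(e) character())
  has_gt <- "GT" %in% geno_names && ncol(vcf) > 0L
  samples <- if (ncol(vcf) > 0L) colnames(vcf) else caller_id
  gt_mat <- if (has_gt) {
    m <- VariantAnnotation::geno(vcf)$GT
    matrix(as.character(m), nrow = n, dimnames = dimnames(m))
  } else {
    matrix("./.", nrow = n, ncol = length(samples),
           dimnames = list(NULL, samples))
  }

  keep <- logical(n); start0 <- integer(n); end0 <- integer(n)
  for (i in seq_len(n)) {
    if (n_alt[i] != 1L) { tally["multiallelic"] <- tally["multiallelic"] + 1L; next }
    a <- alts[i]
    symbolic <- grepl("^<.*>$", a)
    is_del <- if (symbolic) {
      identical(a, "<DEL>") || (!is.na(svtype[i]) && svtype[i] == "DEL")
    } else {
      nchar(refs[i]) > nchar(a) &&
        (is.na(svtype[i]) || svtype[i] == "DEL")
    }
    if (!is_del) { tally["non_del"] <- tally["non_del"] + 1L; next }
    if (symbolic) {
      e <- iend[i]
      if (is.na(e) && !is.na(svlen[i])) e <- pos1[i] + abs(svlen[i])
      if (!is.na(e) && !is.na(svlen[i]) && e != pos1[i] + abs(svlen[i])) {
        tally["end_svlen_conflict"] <- tally["end_svlen_conflict"] + 1L
      }
      if (is.na(e) || e <= pos1[i]) { tally["bad_coord"] <- tally["bad_coord"] + 1L; next }
      start0[i] <- pos1[i]          # POS is the padding base
      end0[i] <- e
    } else {
      dlen <- nchar(refs[i]) - nchar(a)
      start0[i] <- pos1[i]
      end0[i] <- pos1[i] + dlen
    }
    keep[i] <- TRUE
  }

  rows <- list()
  for (i in which(keep)) {
    states <- parse_gt(gt_mat[i, ])
    if (anyNA(states)) { tally["bad_gt"] <- tally["bad_gt"] + 1L; next }
    use <- states != "REF_REF"
    if (length(samples) > 1L) use <- use & states != "MISSING"
    if (!any(use)) next
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom[i], start = start0[i], end = end0[i],
      sample_id = samples[use], caller_id = caller_id,
      genotype = unname(states[use]),
      qual = if (is.na(quals[i])) NA_real_ else quals[i],
      record_id = ids[i], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  if (sum(tally) > 0L) {
    ds_note(sprintf(
      "%s: skipped %d non-DEL, rejected %d multiallelic, %d bad-coordinate, %d bad-genotype record(s)",
      basename(path), tally[["non_del"]], tally[["multiallelic"]],
      tally[["bad_coord"]], tally[["bad_gt"]]))
  }
  validate_intervals(out, "deletion call")
  attr(out, "tally") <- tally
  out
}

vcf_header_lines <- function(samples, contigs = NULL, extra_info = character()) {
  c("##fileformat=VCFv4.2",
    "##source=delscan",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Difference in length between REF and ALT alleles\">",
    extra_info,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contigs),
              as.integer(contigs))
    },
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

# Single-sample caller VCF (simulator output). Calls carry 0-based half-open
# spans; records are written as symbolic <DEL> with POS = start (the padding
# base in 1-based terms) and END = end.
write_caller_vcf <- function(calls, path, sample_id, contigs = NULL) {
  validate_intervals(calls, "deletion call")
  ord <- order(calls$chrom, calls$start, calls$end)
  calls <- calls[ord, , drop = FALSE]
  recs <- sprintf(
    "%s\t%d\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
    calls$chrom, calls$start,
    if (!is.null(calls$record_id)) calls$record_id else sprintf("del%d", seq_len(nrow(calls))),
    "N", "<DEL>",
    ifelse(is.na(calls$qual), ".", format(calls$qual, trim = TRUE, scientific = FALSE)),
    "PASS",
    sprintf("SVTYPE=DEL;END=%d;SVLEN=-%d", calls$end, calls$end - calls$start),
    "GT", format_gt(calls$genotype))
  writeLines(c(vcf_header_lines(sample_id, contigs), recs), path)
  invisible(path)
}

#' Write consensus deletions or deletion loci as a multi-sample VCF
#'
#' Emits VCF 4.2 symbolic `<DEL>` records with `INFO` keys `SVTYPE`, `END`,
#' `SVLEN`, plus `CALLERS` (comma-separated supporting caller identifiers)
#' and `RO` (the matched reciprocal overlap; for loci, the median across
#' members). For a consensus call table, one record is written per distinct
#' interval, with per-sample `GT` filled for the samples carrying exactly
#' that interval and `0/0` elsewhere. For a [cluster_loci()] result, one
#' record is written per locus representative interval.
#'
#' @param x A consensus call `data.frame` (from [intersect_callsets()]) or a
#'   `"deletion_loci"` object (from [cluster_loci()]).
#' @param path Output path.
#' @param samples Optional character vector fixing the sample columns (and
#'   their order); defaults to the sorted samples present in `x`.
#' @return `path`, invisibly.
#' @export
write_consensus_vcf <- function(x, path, samples = NULL) {
  if (inherits(x, "deletion_loci")) {
    reps <- x$loci
    members <- x$genotypes
    if (is.null(samples)) samples <- sort(unique(members$sample_id))
    key <- reps$locus_id
    gts <- matrix("0/0", nrow = nrow(reps), ncol = length(samples),
                  dimnames = list(key, samples))
    gts[cbind(match(members$locus_id, key), match(members$sample_id, samples))] <-
      format_gt(members$genotype)
    ro <- vapply(split(members$matched_ro, members$locus_id)[as.character(key)],
                 median, numeric(1))
    callers <- attr(x, "callers")
    df <- reps
  } else {
    validate_intervals(x, "consensus call")
    if (is.null(samples)) samples <- sort(unique(x$sample_id))
    ukey <- paste(x$chrom, x$start, x$end, sep = ":")
    first <- !duplicated(ukey)
    df <- x[first, c("chrom", "start", "end"), drop = FALSE]
    gts <- matrix("0/0", nrow = nrow(df), ncol = length(samples),
                  dimnames = list(ukey[first], samples))
    gts[cbind(match(ukey, ukey[first]), match(x$sample_id, samples))] <-
      format_gt(x$genotype)
    ro <- vapply(split(x$matched_ro, ukey)[ukey[first]], max, numeric(1))
    callers <- unique(c(x$caller_primary, x$caller_secondary))
  }
  ord <- order(df$chrom, df$start, df$end)
  df <- df[ord, , drop = FALSE]
  gts <- gts[ord, , drop = FALSE]
  ro <- ro[ord]
  if (is.null(callers)) callers <- "NA"
  extra <- c(
    "##INFO=<ID=CALLERS,Number=.,Type=String,Description=\"Callers supporting the consensus\">",
    "##INFO=<ID=RO,Number=1,Type=Float,Description=\"Matched reciprocal overlap\">")
  recs <- sprintf(
    "%s\t%d\tcons%d\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=%d;SVLEN=-%d;CALLERS=%s;RO=%s\tGT\t%s",
    df$chrom, df$start, seq_len(nrow(df)), df$end, df$end - df$start,
    paste(callers, collapse = ","),
    formatC(ro, digits = 4, format = "f"),
    apply(gts, 1L, paste, collapse = "\t"))
  writeLines(c(vcf_header_lines(samples, extra_info = extra), recs), path)
  invisible(path)
}
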