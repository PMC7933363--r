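# Effect classes ordered by priority: a deletion touching a protein-coding
# exon is CODING_EXON regardless of what else it spans, and so on down.
EFFECT_CLASSES <- c("CODING_EXON", "INTRONIC", "REGULATORY", "INTERGENIC")

# Flank-extended gene spans: [start - flank, end + flank), clipped at 0.
flank_spans <- function(genes, flank) {
  data.frame(chrom = genes$chrom,
             start = pmax(0L, genes$start - as.integer(flank)),
             end = genes$end + as.integer(flank),
             stringsAsFactors = FALSE)
}

overlaps_any <- function(query, subject) {
  if (nrow(query) == 0L) return(logical(0))
  if (nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_gr0(query), as_gr0(subject)))
  seq_len(nrow(query)) %in% S4Vectors::queryHits(hits)
}

#' Classify deletions by genomic effect
#'
#' Assigns each interval exactly one effect class against the protein-coding
#' genes of an annotation, resolving multi-gene overlaps by severity
#' priority:
#'
#' 1. `CODING_EXON` — overlaps at least 1 bp of an exon;
#' 2. `INTRONIC` — otherwise overlaps a gene span;
#' 3. `REGULATORY` — otherwise overlaps the `flank` bp immediately up- or
#'    downstream of a gene span (both sides, strand-ignoring);
#' 4. `INTERGENIC` — none of the above.
#'
#' Chromosomes absent from the annotation classify as `INTERGENIC` with a
#' logged notice.
#'
#' @param query Interval table of deletions (or locus representatives).
#' @param annotation An `"sv_annotation"` object.
#' @param flank Regulatory flank in bp.
#' @return Factor vector over levels `CODING_EXON`, `INTRONIC`,
#'   `REGULATORY`, `INTERGENIC`, one per query row.
#' @export
classify_deletions <- function(query, annotation, flank = 1000L) {
  validate_intervals(query)
  if (flank < 0L) ds_stop("flank must be >= 0")
  genes <- pc_genes(annotation)
  exons <- pc_exons(annotation)
  out <- rep("INTERGENIC", nrow(query))
  out[overlaps_any(query, flank_spans(genes, flank))] <- "REGULATORY"
  out[overlaps_any(query, genes)] <- "INTRONIC"
  out[overlaps_any(query, exons)] <- "CODING_EXON"
  missing_chr <- !query$chrom %in% annotation$genes$chrom
  if (any(missing_chr)) {
    ds_note(sprintf("%d interval(s) on chromosome(s) absent from the annotation -> INTERGENIC",
                    sum(missing_chr)))
  }
  factor(out, levels = EFFECT_CLASSES)
}

#' Genes contacted by deletion loci
#'
#' Reports, per locus and protein-coding gene, the strongest contact between
#' the locus representative interval and the gene: `EXON` (overlaps an
#' exon), `INTRON` (overlaps the span but no exon), or `FLANK` (overlaps
#' only the regulatory flank).
#'
#' @param loci A `"deletion_loci"` object, or an interval table with a
#'   `locus_id` column.
#' @param annotation An `"sv_annotation"` object.
#' @param flank Regulatory flank in bp.
#' @return `data.frame(locus_id, gene_id, contact)`, ordered by locus then
#'   gene position.
#' @export
genes_hit <- function(loci, annotation, flank = 1000L) {
  reps <- if (inherits(loci, "deletion_loci")) loci$loci else loci
  validate_intervals(reps)
  if (is.null(reps$locus_id)) reps$locus_id <- sprintf("L%04d", seq_len(nrow(reps)))
  genes <- pc_genes(annotation)
  exons <- pc_exons(annotation)
  empty <- data.frame(locus_id = character(), gene_id = character(),
                      contact = character(), stringsAsFactors = FALSE)
  if (nrow(reps) == 0L || nrow(genes) == 0L) return(empty)
  fl <- flank_spans(genes, flank)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(as_gr0(reps),
                                                       as_gr0(fl)))
  qi <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)
  if (!length(qi)) return(empty)
  contact <- rep("FLANK", length(qi))
  span_ov <- reps$start[qi] < genes$end[gi] & reps$end[qi] > genes$start[gi] &
    reps$chrom[qi] == genes$chrom[gi]
  contact[span_ov] <- "INTRON"
  # Exon contact per (locus, gene) pair.
  ex_pairs <- suppressWarnings(GenomicRanges::findOverlaps(as_gr0(reps),
                                                           as_gr0(exons)))
  ex_key <- paste(S4Vectors::queryHits(ex_pairs),
                  exons$gene_id[S4Vectors::subjectHits(ex_pairs)])
  contact[paste(qi, genes$gene_id[gi]) %in% ex_key] <- "EXON"
  out <- data.frame(locus_id = reps$locus_id[qi],
                    gene_id = genes$gene_id[gi],
                    contact = contact, stringsAsFactors = FALSE)
  out <- out[order(match(out$locus_id, reps$locus_id),
                   genes$start[match(out$gene_id, genes$gene_id)],
                   out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-locus AF used by the catalog gate: either the maximum per-population
# AF (default) or the AF pooled over all populations' called samples.
locus_gate_af <- function(loci, af_mode = c("max", "pooled")) {
  af_mode <- match.arg(af_mode)
  af <- loci$af
  if (af_mode == "max") {
    v <- tapply(af$af, af$locus_id, max, na.rm = TRUE)
    v[!is.finite(v)] <- NA_real_
    return(v)
  }
  alleles <- tapply(af$af * 2 * af$n_called, af$locus_id, sum, na.rm = TRUE)
  called <- tapply(2 * af$n_called, af$locus_id, sum, na.rm = TRUE)
  alleles / pmax(called, 1)
}

#' Allele-frequency-filtered deletion gene catalogs
#'
#' Builds the catalog of protein-coding genes altered by a deletion locus
#' whose maximum per-population allele frequency is strictly greater than
#' `af_threshold`. Genes whose strongest contact is `EXON` or `INTRON` form
#' the main catalog; genes contacted only through the regulatory flank are
#' reported in a separate regulatory catalog.
#'
#' @param loci A `"deletion_loci"` object.
#' @param annotation An `"sv_annotation"` object.
#' @param af_threshold Strict allele-frequency gate.
#' @param flank Regulatory flank in bp.
#' @param af_mode How the gated allele frequency is formed: `"max"`
#'   (default) takes the maximum per-population AF; `"pooled"` pools
#'   deleted alleles over all populations' called samples.
#' @return A list with `genic` and `regulatory` data frames
#'   (`gene_id, gene_name, contact, best_af, locus_id, chrom, start, end`),
#'   each deduplicated by gene and ordered by chromosome, start, gene id.
#' @export
gene_catalog <- function(loci, annotation, af_threshold = 0.05,
                         flank = 1000L, af_mode = c("max", "pooled")) {
  hits <- genes_hit(loci, annotation, flank)
  max_af <- locus_gate_af(loci, af_mode)
  hits$best_af <- unname(max_af[hits$locus_id])
  hits <- hits[!is.na(hits$best_af) & hits$best_af > af_threshold, , drop = FALSE]
  genes <- pc_genes(annotation)
  reps <- loci$loci
  build <- function(h) {
    if (nrow(h) == 0L) {
      return(data.frame(gene_id = character(), gene_name = character(),
                        contact = character(), best_af = numeric(),
                        locus_id = character(), chrom = character(),
                        start = integer(), end = integer(),
                        stringsAsFactors = FALSE))
    }
    # One row per gene: strongest contact, then highest AF.
    sev <- c(EXON = 2L, INTRON = 1L, FLANK = 0L)
    h <- h[order(h$gene_id, -sev[h$contact], -h$best_af), , drop = FALSE]
    h <- h[!duplicated(h$gene_id), , drop = FALSE]
    gi <- match(h$gene_id, genes$gene_id)
    li <- match(h$locus_id, reps$locus_id)
    out <- data.frame(gene_id = h$gene_id,
                      gene_name = genes$gene_name[gi],
                      contact = h$contact, best_af = h$best_af,
                      locus_id = h$locus_id,
                      chrom = reps$chrom[li], start = reps$start[li],
                      end = reps$end[li], stringsAsFactors = FALSE)
    out <- out[order(genes$chrom[gi], genes$start[gi], out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  genic_genes <- unique(hits$gene_id[hits$contact %in% c("EXON", "INTRON")])
  list(genic = build(hits[hits$gene_id %in% genic_genes, , drop = FALSE]),
       regulatory = build(hits[!hits$gene_id %in% genic_genes, , drop = FALSE]))
}

#' Effect-class counts per population
#'
#' Tabulates, for each population, the number of deletion loci segregating
#' in that population (allele frequency > 0) by effect class; the `total`
#' row counts every locus once.
#'
#' @inheritParams gene_catalog
#' @return `data.frame(population, CODING_EXON, INTRONIC, REGULATORY,
#'   INTERGENIC)`, with a final `total` row.
#' @export
effect_counts <- function(loci, annotation, flank = 1000L) {
  cls <- classify_deletions(loci$loci, annotation, flank)
  af <- loci$af
  pops <- sort(unique(af$population))
  rows <- lapply(pops, function(p) {
    seg <- af$locus_id[af$population == p & !is.na(af$af) & af$af > 0]
    tab <- table(cls[loci$loci$locus_id %in% seg])
    data.frame(population = p, as.list(tab), stringsAsFactors = FALSE)
  })
  total <- data.frame(population = "total", as.list(table(cls)),
                      stringsAsFactors = FALSE)
  out <- rbind(do.call(rbind, rows), total)
  rownames(out) <- NULL
  out
}
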