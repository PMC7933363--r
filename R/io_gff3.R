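#' Read a GFF3 gene annotation
#'
#' Imports `gene` and `exon` features from a GFF3 file and assembles a
#' validated annotation object. Exon `Parent` attributes may point at the
#' gene directly or at an intermediate transcript whose own `Parent` is the
#' gene. GFF3 1-based inclusive coordinates are converted to the package's
#' 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @return An object of class `"sv_annotation"`: a list with
#'   * `genes`: `data.frame(gene_id, gene_name, biotype, chrom, start, end,
#'     strand)`;
#'   * `exons`: `data.frame(gene_id, chrom, start, end)`, sorted by start
#'     within gene.
#' @details Hard errors are raised for orphan exons (unresolvable `Parent`)
#'   and for exons extending outside their gene span; overlapping exons
#'   within one gene are also rejected.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) ds_stop("GFF3 not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- as.character(md$ID)
  get_first <- function(x) if (length(x)) x[[1]] else NA_character_
  parents <- if ("Parent" %in% names(md)) {
    vapply(as.list(md$Parent), function(p) if (length(p)) as.character(p)[1] else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))

  gi <- which(type == "gene")
  if (!length(gi)) ds_stop("no gene features in ", path)
  biotype <- rep(NA_character_, length(gr))
  for (col in c("gene_biotype", "biotype", "gene_type")) {
    if (col %in% names(md)) {
      v <- as.character(md[[col]])
      biotype[is.na(biotype)] <- v[is.na(biotype)]
    }
  }
  gname <- if ("Name" %in% names(md)) as.character(md$Name) else ids
  genes <- data.frame(
    gene_id = ids[gi],
    gene_name = ifelse(is.na(gname[gi]), ids[gi], gname[gi]),
    biotype = ifelse(is.na(biotype[gi]), "protein_coding", biotype[gi]),
    chrom = as.character(GenomicRanges::seqnames(gr))[gi],
    start = GenomicRanges::start(gr)[gi] - 1L,
    end = GenomicRanges::end(gr)[gi],
    strand = as.character(GenomicRanges::strand(gr))[gi],
    stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id)) ds_stop("duplicate gene IDs in ", path)

  # Map every feature id to its gene: climb Parent links (exon -> mRNA ->
  # gene or exon -> gene).
  id2parent <- setNames(parents, ids)
  resolve_gene <- function(pid) {
    seen <- 0L
    while (!is.na(pid) && !pid %in% genes$gene_id && seen < 5L) {
      pid <- if (pid %in% names(id2parent)) id2parent[[pid]] else NA_character_
      seen <- seen + 1L
    }
    if (is.na(pid) || !pid %in% genes$gene_id) NA_character_ else pid
  }
  ei <- which(type == "exon")
  exon_gene <- vapply(parents[ei], resolve_gene, character(1), USE.NAMES = FALSE)
  if (anyNA(exon_gene)) {
    ds_stop("orphan exon: Parent cannot be resolved to a gene (exon #",
            which(is.na(exon_gene))[1], ")")
  }
  exons <- data.frame(
    gene_id = exon_gene,
    chrom = as.character(GenomicRanges::seqnames(gr))[ei],
    start = GenomicRanges::start(gr)[ei] - 1L,
    end = GenomicRanges::end(gr)[ei],
    stringsAsFactors = FALSE)
  sv_annotation(genes, exons)
}

#' Construct an annotation object from gene and exon tables
#'
#' Lower-level constructor behind [read_gff3()]; useful for building small
#' annotations directly in tests and simulations. Validates that every exon
#' lies within its gene span and that exons of one gene do not overlap.
#'
#' @param genes `data.frame` with columns `gene_id`, `chrom`, `start`, `end`
#'   and optionally `gene_name`, `biotype` (default `"protein_coding"`),
#'   `strand` (default `"+"`).
#' @param exons `data.frame` with columns `gene_id`, `chrom`, `start`, `end`.
#'   Genes without exon rows get a single exon covering their span.
#' @return An object of class `"sv_annotation"`.
#' @export
sv_annotation <- function(genes, exons = NULL) {
  if (is.null(genes$gene_name)) genes$gene_name <- genes$gene_id
  if (is.null(genes$biotype)) genes$biotype <- "protein_coding"
  if (is.null(genes$strand)) genes$strand <- "+"
  genes <- genes[, c("gene_id", "gene_name", "biotype", "chrom", "start",
                     "end", "strand")]
  genes$start <- as.integer(genes$start); genes$end <- as.integer(genes$end)
  validate_intervals(genes, "gene")
  if (is.null(exons)) {
    exons <- genes[, c("gene_id", "chrom", "start", "end")]
  }
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  validate_intervals(exons, "exon")
  missing_ex <- setdiff(genes$gene_id, exons$gene_id)
  if (length(missing_ex)) {
    add <- genes[genes$gene_id %in% missing_ex, c("gene_id", "chrom", "start", "end")]
    exons <- rbind(exons, add)
  }
  if (!all(exons$gene_id %in% genes$gene_id)) {
    ds_stop("exon with unknown gene_id: ",
            setdiff(exons$gene_id, genes$gene_id)[1])
  }
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ]
  rownames(exons) <- NULL
  gidx <- match(exons$gene_id, genes$gene_id)
  outside <- exons$start < genes$start[gidx] | exons$end > genes$end[gidx] |
    exons$chrom != genes$chrom[gidx]
  if (any(outside)) {
    ds_stop("exon outside gene span for gene ", exons$gene_id[which(outside)[1]])
  }
  for (g in unique(exons$gene_id[duplicated(exons$gene_id)])) {
    e <- exons[exons$gene_id == g, ]
    if (any(e$start[-1] < e$end[-nrow(e)])) {
      ds_stop("overlapping exons within gene ", g)
    }
  }
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), ]
  rownames(genes) <- NULL
  structure(list(genes = genes, exons = exons), class = "sv_annotation")
}

#' @export
print.sv_annotation <- function(x, ...) {
  cat(sprintf("annotation: %d genes (%d protein-coding), %d exons, %d chromosome(s)\n",
              nrow(x$genes), sum(x$genes$biotype == "protein_coding"),
              nrow(x$exons), length(unique(x$genes$chrom))))
  invisible(x)
}

# Protein-coding subset used by all effect logic.
pc_genes <- function(annotation) {
  annotation$genes[annotation$genes$biotype == "protein_coding", , drop = FALSE]
}

pc_exons <- function(annotation) {
  pcg <- pc_genes(annotation)$gene_id
  annotation$exons[annotation$exons$gene_id %in% pcg, , drop = FALSE]
}

# Write an annotation back out as GFF3 (1-based inclusive coordinates).
# Exons are attached directly to their gene via Parent.
write_gff3 <- function(annotation, path) {
  g <- annotation$genes
  e <- annotation$exons
  lines <- character(0)
  for (i in seq_len(nrow(g))) {
    lines <- c(lines, sprintf(
      "%s\tdelscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;gene_biotype=%s",
      g$chrom[i], g$start[i] + 1L, g$end[i], g$strand[i],
      g$gene_id[i], g$gene_name[i], g$biotype[i]))
    ex <- e[e$gene_id == g$gene_id[i], , drop = FALSE]
    if (nrow(ex)) {
      lines <- c(lines, sprintf(
        "%s\tdelscan\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
        ex$chrom, ex$start + 1L, ex$end, g$strand[i],
        g$gene_id[i], seq_len(nrow(ex)), g$gene_id[i]))
    }
  }
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
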