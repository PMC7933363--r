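#' Run the full deletion-consensus pipeline on a simulated cohort
#'
#' Orchestrates every stage over one [sim_config()] cohort: simulate and
#' write the input files (GFF3 annotation, per-sample per-caller VCFs, GMT
#' gene sets, truth tables), read them back through the package readers,
#' size-filter both callers' calls, intersect them per sample, cluster
#' consensus calls into loci, classify effects and build the gene catalogs,
#' tabulate per-sample and per-population allelic states, compute the
#' caller-agreement correlation, and test the catalog for gene-set
#' enrichment. All tabular artifacts and a machine-readable run manifest
#' are written under `out_dir`.
#'
#' Identical `config` (including seed) yields byte-identical artifacts.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Output directory (created if needed).
#' @param io `"files"` routes the simulated calls through VCF/GFF3 files
#'   and the package readers (the full pipeline contract); `"memory"`
#'   skips the file round-trip for speed in repeated simulation studies.
#' @return A list of class `"delscan_run"` with elements `cohort`,
#'   `annotation`, `calls`, `filtered`, `consensus`, `loci`, `effects`,
#'   `catalog`, `sample_counts`, `population_summary`, `caller_r2`,
#'   `enrichment`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir, io = c("files", "memory")) {
  io <- match.arg(io)
  params <- config$params
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(
    config, dir = if (io == "files") file.path(out_dir, "input") else NULL)
  s2p <- sample_populations(config)
  samples <- config_samples(config)
  caller_ids <- names(cohort$calls)
  if (!params$primary_caller %in% caller_ids) {
    ds_stop("primary_caller '", params$primary_caller,
            "' is not among the simulated callers: ",
            paste(caller_ids, collapse = ", "))
  }
  secondary_id <- setdiff(caller_ids, params$primary_caller)[1]

  if (io == "files") {
    annotation <- read_gff3(cohort$files$gff3)
    gene_sets <- read_gmt(cohort$files$gmt)
    calls <- lapply(caller_ids, function(cl) {
      do.call(rbind, lapply(samples, function(s) {
        read_deletions_vcf(cohort$files$vcf[[paste(s, cl, sep = ".")]],
                           caller_id = cl)
      }))
    })
    names(calls) <- caller_ids
  } else {
    annotation <- cohort$annotation
    gene_sets <- cohort$gene_sets
    calls <- cohort$calls
  }
  n_parsed <- vapply(calls, nrow, integer(1))

  filtered <- lapply(calls, size_filter, min_len = params$min_len,
                     max_len = params$max_len)
  raw_counts <- lapply(filtered, raw_call_counts, samples = samples)
  caller_r2 <- caller_count_correlation(raw_counts[[1]], raw_counts[[2]])

  consensus <- do.call(rbind, lapply(samples, function(s) {
    pick <- function(df) df[df$sample_id == s, , drop = FALSE]
    intersect_callsets(pick(filtered[[params$primary_caller]]),
                       pick(filtered[[secondary_id]]),
                       ro_threshold = params$ro_threshold)
  }))
  rownames(consensus) <- NULL

  loci <- cluster_loci(consensus, s2p, ro_threshold = params$ro_threshold)
  effects <- effect_counts(loci, annotation, params$flank)
  catalog <- gene_catalog(loci, annotation, params$af_threshold,
                          params$flank)
  sample_counts <- per_sample_counts(consensus, s2p)
  pop_summary <- population_summary(sample_counts)
  enrichment <- enrich_sets(catalog$genic$gene_id, gene_sets,
                            pc_genes(annotation)$gene_id, params$alpha)

  manifest <- list(
    tool = "delscan",
    version = as.character(packageVersion("delscan")),
    seed = config$seed,
    params = unclass(params),
    populations = as.list(config$populations),
    counts = list(
      parsed = as.list(n_parsed),
      size_filtered = as.list(vapply(filtered, nrow, integer(1))),
      consensus = nrow(consensus),
      loci = nrow(loci$loci),
      catalog_genes = nrow(catalog$genic),
      regulatory_genes = nrow(catalog$regulatory),
      significant_sets = sum(enrichment$significant)),
    caller_r2 = caller_r2)

  write_consensus_vcf(consensus, file.path(out_dir, "consensus.vcf"),
                      samples = samples)
  write_consensus_vcf(loci, file.path(out_dir, "loci.vcf"),
                      samples = samples)
  write_bed(loci$loci[, c("chrom", "start", "end")],
            file.path(out_dir, "loci.bed"))
  write_tsv(loci_table(loci), file.path(out_dir, "loci.tsv"))
  write_tsv(effects, file.path(out_dir, "effect_counts.tsv"))
  write_tsv(catalog$genic, file.path(out_dir, "gene_catalog.tsv"))
  write_tsv(catalog$regulatory, file.path(out_dir, "regulatory_catalog.tsv"))
  write_tsv(sample_counts, file.path(out_dir, "sample_counts.tsv"))
  write_tsv(pop_summary, file.path(out_dir, "population_summary.tsv"))
  write_tsv(enrichment, file.path(out_dir, "enrichment.tsv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  structure(list(cohort = cohort, annotation = annotation, calls = calls,
                 filtered = filtered, consensus = consensus, loci = loci,
                 effects = effects, catalog = catalog,
                 sample_counts = sample_counts,
                 population_summary = pop_summary,
                 caller_r2 = caller_r2, enrichment = enrichment,
                 manifest = manifest),
            class = "delscan_run")
}

#' @export
print.delscan_run <- function(x, ...) {
  m <- x$manifest$counts
  cat("delscan pipeline run\n")
  cat(sprintf("  consensus calls   %d\n", m$consensus))
  cat(sprintf("  deletion loci     %d\n", m$loci))
  cat(sprintf("  catalog genes     %d (+%d regulatory-only)\n",
              m$catalog_genes, m$regulatory_genes))
  cat(sprintf("  caller R^2        %.3f\n", x$caller_r2))
  cat(sprintf("  significant sets  %d\n", m$significant_sets))
  invisible(x)
}

#' Recovery and precision of a pipeline run against the generator truth
#'
#' Scores consensus output against the planted truth. Recovery is counted
#' per carrier pair: for every truth deletion within the size gate and
#' every sample carrying a non-reference genotype for it, the pair is
#' recovered when that sample has a consensus call with reciprocal overlap
#' at or above the threshold with the truth interval. False-positive loci
#' are loci whose representative matches no truth deletion at the
#' threshold.
#'
#' @param run A `"delscan_run"` object.
#' @return List with `n_pairs`, `n_recovered`, `recovery` (fraction),
#'   `n_loci`, `n_fp_loci`.
#' @export
recovery_stats <- function(run) {
  config <- run$cohort$config
  params <- config$params
  truth <- run$cohort$truth
  dels <- truth$deletions
  len <- dels$end - dels$start
  in_range <- dels[len >= params$min_len & len <= params$max_len, ,
                   drop = FALSE]
  geno <- truth$genotypes
  carriers <- geno[geno$genotype != "REF_REF" &
                     geno$truth_id %in% in_range$truth_id, , drop = FALSE]
  cons <- run$consensus
  hit <- logical(nrow(carriers))
  if (nrow(cons)) {
    ti <- match(carriers$truth_id, in_range$truth_id)
    for (k in seq_len(nrow(carriers))) {
      cc <- cons[cons$sample_id == carriers$sample_id[k], , drop = FALSE]
      if (!nrow(cc)) next
      ro <- reciprocal_overlap(in_range[ti[k], c("chrom", "start", "end")],
                               cc[, c("chrom", "start", "end")])
      hit[k] <- any(ro >= params$ro_threshold)
    }
  }
  reps <- run$loci$loci
  fp <- logical(nrow(reps))
  for (k in seq_len(nrow(reps))) {
    ro <- reciprocal_overlap(reps[k, c("chrom", "start", "end")],
                             dels[, c("chrom", "start", "end")])
    fp[k] <- !any(ro >= params$ro_threshold)
  }
  list(n_pairs = nrow(carriers), n_recovered = sum(hit),
       recovery = if (nrow(carriers)) sum(hit) / nrow(carriers) else NA_real_,
       n_loci = nrow(reps), n_fp_loci = sum(fp))
}
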