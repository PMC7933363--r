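#!/usr/bin/env Rscript
# Stage 5: gene-set enrichment of the deletion gene catalog.
#
# Tests the AF > 5% gene catalog for over-representation in each gene set
# (hypergeometric upper tail against the protein-coding background), with
# Benjamini-Hochberg adjustment across sets and significance declared at
# q < 0.05.

source("analysis/_common.R")

st <- load_consensus()
cfg <- st$cfg
catalog <- gene_catalog(st$loci, st$annotation, cfg$params$af_threshold,
                        cfg$params$flank)
gene_sets <- read_gmt(file.path(DATA_DIR, "gene_sets.gmt"))
background <- st$annotation$genes$gene_id[
  st$annotation$genes$biotype == "protein_coding"]

res <- enrich_sets(catalog$genic$gene_id, gene_sets, background,
                   cfg$params$alpha)
message(sprintf("tested %d gene sets against %d query genes (background %d)",
                nrow(res), res$n[1], res$N[1]))
print(utils::head(res, 5))
message(sprintf("%d set(s) significant at q < %g", sum(res$significant),
                cfg$params$alpha))

delscan:::write_tsv(res, file.path(TABLE_DIR, "enrichment.tsv"))
message("wrote enrichment.tsv")
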