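#!/usr/bin/env Rscript
# Stage 3: effect classification and the deletion gene catalog.
#
# Classifies every deletion locus against the gene annotation (coding exon
# > intronic > 1 kb regulatory flank > intergenic), tabulates effect-class
# counts per population, and builds the catalog of protein-coding genes hit
# by a deletion with maximum per-population allele frequency > 5%.

source("analysis/_common.R")

st <- load_consensus()
cfg <- st$cfg

counts <- effect_counts(st$loci, st$annotation, cfg$params$flank)
print(counts)
catalog <- gene_catalog(st$loci, st$annotation, cfg$params$af_threshold,
                        cfg$params$flank)
message(sprintf("%d genes carry a deletion (exon or intron contact) at AF > %g",
                nrow(catalog$genic), cfg$params$af_threshold))
message(sprintf("%d further genes are contacted only through the %d bp flank",
                nrow(catalog$regulatory), cfg$params$flank))

delscan:::write_tsv(counts, file.path(TABLE_DIR, "effect_counts.tsv"))
delscan:::write_tsv(catalog$genic, file.path(TABLE_DIR, "gene_catalog.tsv"))
delscan:::write_tsv(catalog$regulatory,
                    file.path(TABLE_DIR, "regulatory_catalog.tsv"))
message("wrote effect_counts.tsv, gene_catalog.tsv, regulatory_catalog.tsv")
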