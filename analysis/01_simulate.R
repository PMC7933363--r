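#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Generates the gene annotation, 300 truth deletions with per-population
# allele frequencies and planted effect classes, and per-sample VCFs from
# two error-prone callers, writing everything under results/data/.

source("analysis/_common.R")

cfg <- the_config()
cohort <- simulate_cohort(cfg, dir = DATA_DIR)

d <- cohort$truth$deletions
message(sprintf("simulated %d genes over %d chromosomes",
                nrow(cohort$annotation$genes),
                length(cfg$chrom_sizes)))
message(sprintf("planted %d truth deletions: %s", nrow(d),
                paste(sprintf("%s=%d", names(table(d$class)),
                              table(d$class)), collapse = ", ")))
len <- d$end - d$start
message(sprintf("%d deletions fall inside the 500 bp - 100 kb analysis gate",
                sum(len >= cfg$params$min_len & len <= cfg$params$max_len)))
for (cl in names(cohort$calls)) {
  x <- cohort$calls[[cl]]
  message(sprintf("%s emitted %d calls (%d false positives)", cl, nrow(x),
                  sum(x$is_fp)))
}
message("inputs written under ", DATA_DIR)
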