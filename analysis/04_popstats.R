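#!/usr/bin/env Rscript
# Stage 4: allelic-state tabulation and caller agreement.
#
# Counts heterozygous and homozygous consensus deletions per sample,
# summarises the within-population variability of those counts, and
# measures agreement between the two callers as the squared Pearson
# correlation of their per-sample (size-filtered) call counts.

source("analysis/_common.R")

st <- load_consensus()
counts <- per_sample_counts(st$consensus, st$s2p)
summ <- population_summary(counts)
print(summ)
most_var <- summ$population[which.max(pmax(summ$sd_het, summ$sd_hom))]
message(sprintf("most variable population by either allelic state: %s",
                most_var))

raw <- lapply(st$filtered, function(x)
  delscan:::raw_call_counts(x, names(st$s2p)))
r2 <- caller_count_correlation(raw[[1]], raw[[2]])
message(sprintf("caller agreement on per-sample call counts: R^2 = %.3f", r2))

delscan:::write_tsv(counts, file.path(TABLE_DIR, "sample_counts.tsv"))
delscan:::write_tsv(summ, file.path(TABLE_DIR, "population_summary.tsv"))
message("wrote sample_counts.tsv, population_summary.tsv")
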