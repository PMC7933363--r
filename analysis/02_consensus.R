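#!/usr/bin/env Rscript
# Stage 2: dual-caller consensus and cross-sample deletion loci.
#
# Reads the per-sample VCFs from both callers, applies the 500 bp - 100 kb
# size gate, keeps deletions supported by both callers at >= 50% reciprocal
# overlap, and clusters the per-sample consensus calls into population-wide
# loci with per-population allele frequencies.

source("analysis/_common.R")

st <- load_consensus()
message(sprintf("parsed calls: %s",
                paste(sprintf("%s=%d", names(st$calls),
                              vapply(st$calls, nrow, 1L)), collapse = ", ")))
message(sprintf("after size gate: %s",
                paste(sprintf("%s=%d", names(st$filtered),
                              vapply(st$filtered, nrow, 1L)), collapse = ", ")))
message(sprintf("%d consensus calls across %d samples",
                nrow(st$consensus), length(unique(st$consensus$sample_id))))
message(sprintf("%d deletion loci after single-linkage clustering",
                nrow(st$loci$loci)))

write_consensus_vcf(st$consensus, file.path(TABLE_DIR, "consensus.vcf"),
                    samples = names(st$s2p))
write_consensus_vcf(st$loci, file.path(TABLE_DIR, "loci.vcf"),
                    samples = names(st$s2p))
write_bed(st$loci$loci[, c("chrom", "start", "end")],
          file.path(TABLE_DIR, "loci.bed"))
delscan:::write_tsv(delscan:::loci_table(st$loci),
                    file.path(TABLE_DIR, "loci.tsv"))
message("wrote consensus.vcf, loci.vcf, loci.bed, loci.tsv under ", TABLE_DIR)
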