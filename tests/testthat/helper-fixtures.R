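# Shared fixtures built in code.

# Two-gene annotation used by the effect-classifier tests:
#   geneA chr1 [10000, 20000): exons [10000,10500), [15000,15500), [19500,20000)
#   geneB chr1 [50000, 60000): single exon spanning the gene
#   geneNC chr2: non-coding gene (ignored by effect logic)
toy_annotation <- function() {
  genes <- data.frame(
    gene_id = c("geneA", "geneB", "geneNC"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(10000L, 50000L, 1000L),
    end = c(20000L, 60000L, 2000L),
    biotype = c("protein_coding", "protein_coding", "lncRNA"),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("geneA", "geneA", "geneA", "geneB", "geneNC"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(10000L, 15000L, 19500L, 50000L, 1000L),
    end = c(10500L, 15500L, 20000L, 60000L, 2000L),
    stringsAsFactors = FALSE)
  sv_annotation(genes, exons)
}

# Noise-free caller pair: perfect sensitivity, no jitter, no false
# positives, no genotype errors.
noisefree_profiles <- function() {
  list(caller_profile("manta", sensitivity = 1, fp_per_sample = 0,
                      jitter_bp = 0L, genotype_error_rate = 0),
       caller_profile("lumpy", sensitivity = 1, fp_per_sample = 0,
                      jitter_bp = 0L, genotype_error_rate = 0))
}

# Small fast cohort for simulation-heavy tests.
small_config <- function(seed, ...) {
  sim_config(seed = seed,
             chrom_sizes = c(chr1 = 8000000L, chr2 = 8000000L),
             n_genes = 80L,
             populations = c(Pachon = 4L, Tinaja = 4L, RioChoy = 4L),
             n_truth = 120L, ...)
}
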