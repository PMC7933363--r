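# Shared setup for the numbered analysis drivers. Each driver is
# self-contained: it sources this file, rebuilds what it needs from the
# files written by 01_simulate.R, and writes its own tables under results/.

suppressPackageStartupMessages(library(delscan))

DATA_DIR <- "results/data"
TABLE_DIR <- "results/tables"
dir.create(TABLE_DIR, recursive = TRUE, showWarnings = FALSE)

# One study configuration for the whole analysis: the default cohort
# (3 populations x 8 samples, 300 truth deletions) observed through the
# default noisy caller pair.
the_config <- function() sim_config(seed = 1L)

require_data <- function() {
  if (!dir.exists(DATA_DIR)) {
    stop("simulated inputs not found under ", DATA_DIR,
         " -- run analysis/01_simulate.R first", call. = FALSE)
  }
}

# Read the simulated inputs back through the package readers and rebuild
# the consensus call set and deletion loci.
load_consensus <- function(cfg = the_config()) {
  require_data()
  s2p <- sample_populations(cfg)
  samples <- names(s2p)
  callers <- names(cfg$profiles)
  calls <- lapply(callers, function(cl) {
    do.call(rbind, lapply(samples, function(s) {
      suppressMessages(read_deletions_vcf(
        file.path(DATA_DIR, "vcf", sprintf("%s.%s.vcf", s, cl)), cl))
    }))
  })
  names(calls) <- callers
  filtered <- lapply(calls, function(x) {
    suppressMessages(size_filter(x, cfg$params$min_len, cfg$params$max_len))
  })
  primary <- cfg$params$primary_caller
  secondary <- setdiff(callers, primary)[1]
  consensus <- do.call(rbind, lapply(samples, function(s) {
    intersect_callsets(
      filtered[[primary]][filtered[[primary]]$sample_id == s, ],
      filtered[[secondary]][filtered[[secondary]]$sample_id == s, ],
      cfg$params$ro_threshold)
  }))
  list(cfg = cfg, s2p = s2p, calls = calls, filtered = filtered,
       consensus = consensus,
       loci = cluster_loci(consensus, s2p, cfg$params$ro_threshold),
       annotation = read_gff3(file.path(DATA_DIR, "annotation.gff3")))
}
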