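# Synthetic cohort generator. Everything is driven by one integer seed in
# the config; per-(caller, sample) substreams are derived from it so that a
# caller's output for a sample does not depend on how many other samples
# were simulated.

derive_seed <- function(seed, ...) {
  parts <- unlist(list(...))
  h <- as.double(seed %% 2147483647L)
  for (p in parts) {
    for (v in utf8ToInt(as.character(p))) {
      h <- (h * 131 + v) %% 2147483647
    }
  }
  as.integer(h)
}

#' Caller error profile
#'
#' Describes one simulated structural-variant caller: how often it detects
#' a true deletion present in a sample, how far its breakpoints stray, how
#' often it miscalls the genotype, and how many false-positive calls it
#' produces per sample (with a log-normal size model). The two default
#' profiles mimic the qualitative contrast between a split-read caller that
#' over-calls many short deletions and an assembly-based caller that emits
#' fewer, longer spurious calls.
#'
#' @param caller_id Caller name.
#' @param sensitivity Per-sample detection probability for a true deletion,
#'   in \[0, 1\].
#' @param fp_per_sample Expected (Poisson) false-positive count per sample.
#' @param fp_size_log10_mean,fp_size_log10_sd Log10-normal size model for
#'   false-positive calls.
#' @param jitter_bp Maximum uniform breakpoint shift applied independently
#'   to each end of an emitted call.
#' @param genotype_error_rate Probability of flipping HET and HOM in an
#'   emitted genotype.
#' @return A list of class `"caller_profile"`.
#' @export
caller_profile <- function(caller_id,
                           sensitivity = 0.85,
                           fp_per_sample = 30,
                           fp_size_log10_mean = 2.9,
                           fp_size_log10_sd = 0.4,
                           jitter_bp = 50L,
                           genotype_error_rate = 0.02) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            genotype_error_rate >= 0, genotype_error_rate <= 1,
            jitter_bp >= 0, fp_per_sample >= 0)
  structure(list(caller_id = caller_id, sensitivity = sensitivity,
                 fp_per_sample = fp_per_sample,
                 fp_size_log10_mean = fp_size_log10_mean,
                 fp_size_log10_sd = fp_size_log10_sd,
                 jitter_bp = as.integer(jitter_bp),
                 genotype_error_rate = genotype_error_rate),
            class = "caller_profile")
}

default_profiles <- function() {
  list(
    manta = caller_profile("manta", sensitivity = 0.80, fp_per_sample = 8,
                           fp_size_log10_mean = 3.6, fp_size_log10_sd = 0.4,
                           jitter_bp = 50L, genotype_error_rate = 0.02),
    lumpy = caller_profile("lumpy", sensitivity = 0.85, fp_per_sample = 30,
                           fp_size_log10_mean = 2.9, fp_size_log10_sd = 0.4,
                           jitter_bp = 50L, genotype_error_rate = 0.02))
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort: genome geometry, gene count,
#' populations and their sample sizes, the number and size distribution of
#' planted truth deletions, their effect-class mix and allele-frequency
#' model, the two caller profiles, and the planted-enrichment gene-set
#' design. All randomness flows from `seed`.
#'
#' Defaults describe the study conditions exercised throughout the package:
#' three populations of eight diploid samples, 300 truth deletions with
#' log-uniform sizes from 100 bp to 200 kb (deliberately extending beyond
#' the 500 bp / 100 kb analysis gate so the size filter is exercised), an
#' effect-class mix of 20% coding / 30% intronic / 20% regulatory / 30%
#' intergenic, and per-population allele frequencies that are 0 with
#' probability 0.3 (population-absent deletions) and Beta(0.4, 1.6)
#' otherwise.
#'
#' @param seed Integer master seed.
#' @param chrom_sizes Named integer vector of chromosome lengths (bp).
#' @param n_genes Number of protein-coding genes to place.
#' @param populations Named integer vector: samples per population.
#' @param n_truth Number of planted truth deletions.
#' @param truth_size_range Length-2 numeric: log-uniform size bounds (bp).
#' @param effect_mix Named numeric over `CODING_EXON`, `INTRONIC`,
#'   `REGULATORY`, `INTERGENIC`; proportions of planted classes.
#' @param af_beta Length-2 shape parameters of the Beta allele-frequency
#'   draw.
#' @param af_zero_prob Probability that a population does not carry a given
#'   deletion at all.
#' @param min_gap Minimum distance (bp) between planted truth deletions.
#' @param profiles List of two [caller_profile()] objects.
#' @param set_size,n_decoy_sets,set_truth_prob Planted-enrichment design:
#'   size of every gene set, number of unenriched decoy sets, and the
#'   probability that a member of the planted set is drawn from the
#'   deletion-affected genes rather than the background.
#' @param params [pipeline_params()] the cohort is meant to be analysed
#'   with (used only to place false positives away from truth calls).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_sizes = c(chr1 = 15000000L, chr2 = 15000000L,
                                       chr3 = 15000000L),
                       n_genes = 300L,
                       populations = c(Pachon = 8L, Tinaja = 8L,
                                       RioChoy = 8L),
                       n_truth = 300L,
                       truth_size_range = c(100, 200000),
                       effect_mix = c(CODING_EXON = 0.2, INTRONIC = 0.3,
                                      REGULATORY = 0.2, INTERGENIC = 0.3),
                       af_beta = c(0.4, 1.6),
                       af_zero_prob = 0.3,
                       min_gap = 1000L,
                       profiles = default_profiles(),
                       set_size = 20L,
                       n_decoy_sets = 25L,
                       set_truth_prob = 0.75,
                       params = pipeline_params()) {
  seed <- as.integer(seed)
  if (is.na(seed)) ds_stop("seed must be an integer")
  stopifnot(all(chrom_sizes > 0), n_genes >= 0, all(populations > 0),
            n_truth >= 0, truth_size_range[1] > 0,
            truth_size_range[1] <= truth_size_range[2],
            abs(sum(effect_mix) - 1) < 1e-8, min_gap >= 0)
  if (length(profiles) != 2L) ds_stop("exactly two caller profiles required")
  structure(list(seed = seed, chrom_sizes = chrom_sizes, n_genes = n_genes,
                 populations = populations, n_truth = n_truth,
                 truth_size_range = truth_size_range,
                 effect_mix = effect_mix[EFFECT_CLASSES],
                 af_beta = af_beta, af_zero_prob = af_zero_prob,
                 min_gap = as.integer(min_gap), profiles = profiles,
                 set_size = as.integer(set_size),
                 n_decoy_sets = as.integer(n_decoy_sets),
                 set_truth_prob = set_truth_prob,
                 params = params),
            class = "sim_config")
}

# Sample ids: <population>_<index>, in population order.
config_samples <- function(config) {
  unlist(lapply(names(config$populations), function(p) {
    sprintf("%s_%d", p, seq_len(config$populations[[p]]))
  }), use.names = FALSE)
}

#' @rdname sim_config
#' @param config A `"sim_config"` object.
#' @return `sample_populations()` returns the named sample-to-population
#'   map for the configured cohort.
#' @export
sample_populations <- function(config) {
  samples <- config_samples(config)
  setNames(sub("_[0-9]+$", "", samples), samples)
}

#' Simulate a gene annotation
#'
#' Places non-overlapping protein-coding genes along the configured
#' chromosomes, each with 2-8 non-overlapping exons separated by introns.
#' Genes are separated by at least 2 kb plus both flanks so every effect
#' class has room to be planted. Deterministic given the config seed.
#'
#' @param config A [sim_config()] object.
#' @return An `"sv_annotation"` object.
#' @export
simulate_annotation <- function(config) {
  set.seed(derive_seed(config$seed, "annotation"))
  chroms <- names(config$chrom_sizes)
  n_per <- table(factor(
    sample(chroms, config$n_genes, replace = TRUE,
           prob = config$chrom_sizes / sum(config$chrom_sizes)),
    levels = chroms))
  genes <- list(); exons <- list(); gid <- 0L
  for (ch in chroms) {
    pos <- 10000L
    for (i in seq_len(n_per[[ch]])) {
      gid <- gid + 1L
      n_ex <- sample(2:8, 1L)
      ex_len <- sample(100:400, n_ex, replace = TRUE)
      in_len <- sample(2000:12000, n_ex - 1L, replace = TRUE)
      span <- sum(ex_len) + sum(in_len)
      gap <- sample(25000:60000, 1L)
      start <- pos + gap
      if (start + span + 10000L > config$chrom_sizes[[ch]]) {
        ds_stop("cannot pack ", config$n_genes,
                " genes; increase chromosome sizes")
      }
      offs <- cumsum(c(0L, as.integer(ex_len[-n_ex] + in_len)))
      id <- sprintf("gene%04d", gid)
      genes[[gid]] <- data.frame(
        gene_id = id, gene_name = sprintf("gn%04d", gid),
        biotype = "protein_coding", chrom = ch,
        start = start, end = start + span,
        strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
      exons[[gid]] <- data.frame(
        gene_id = id, chrom = ch, start = start + offs,
        end = start + offs + ex_len, stringsAsFactors = FALSE)
      pos <- start + span
    }
  }
  if (gid == 0L) {
    empty_genes <- data.frame(
      gene_id = character(), gene_name = character(), biotype = character(),
      chrom = character(), start = integer(), end = integer(),
      strand = character(), stringsAsFactors = FALSE)
    return(sv_annotation(empty_genes, empty_genes[, c("gene_id", "chrom",
                                                      "start", "end")]))
  }
  sv_annotation(do.call(rbind, genes), do.call(rbind, exons))
}

# Draw a deletion size log-uniformly within [lo, hi].
draw_size <- function(lo, hi) {
  max(1L, as.integer(round(10^runif(1, log10(lo), log10(hi)))))
}

# Uniform draw from an integer range given as (lo, hi); NULL when empty.
draw_in <- function(lo, hi) {
  if (hi < lo) return(NULL)
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

# Propose an interval intended to classify as `class`. Placement is
# verified against classify_deletions() afterwards (rejection sampling), so
# these only have to succeed often, not always.
propose_interval <- function(class, annotation, config) {
  lo <- config$truth_size_range[1]; hi <- config$truth_size_range[2]
  genes <- pc_genes(annotation); exons <- annotation$exons
  flank <- config$params$flank
  if (class == "CODING_EXON" && nrow(exons)) {
    e <- exons[sample.int(nrow(exons), 1L), ]
    size <- draw_size(lo, hi)
    # Anywhere overlapping the exon by >= 1 bp.
    start <- draw_in(e$start - size + 1L, e$end - 1L)
    if (is.null(start)) return(NULL)
    return(list(chrom = e$chrom, start = start, end = start + size))
  }
  if (class == "INTRONIC" && nrow(genes)) {
    g <- genes[sample.int(nrow(genes), 1L), ]
    ex <- exons[exons$gene_id == g$gene_id, ]
    if (nrow(ex) < 2L) return(NULL)
    i <- sample.int(nrow(ex) - 1L, 1L)
    ilo <- ex$end[i] + 1L; ihi <- ex$start[i + 1L] - 1L   # strict interior
    if (ihi - ilo < lo + 2L) return(NULL)
    size <- draw_size(lo, min(hi, ihi - ilo - 1L))
    start <- draw_in(ilo, ihi - size)
    if (is.null(start)) return(NULL)
    return(list(chrom = g$chrom, start = start, end = start + size))
  }
  if (class == "REGULATORY" && nrow(genes)) {
    g <- genes[sample.int(nrow(genes), 1L), ]
    size <- draw_size(lo, hi)
    if (runif(1) < 0.5) {  # upstream of span: end inside (start-flank, start]
      endp <- draw_in(g$start - flank + 1L, g$start)
      if (is.null(endp)) return(NULL)
      start <- endp - size
    } else {               # downstream: start inside [end, end+flank)
      start <- draw_in(g$end, g$end + flank - 1L)
      if (is.null(start)) return(NULL)
    }
    return(list(chrom = g$chrom, start = start, end = start + size))
  }
  ch <- sample(names(config$chrom_sizes), 1L,
               prob = config$chrom_sizes / sum(config$chrom_sizes))
  size <- draw_size(lo, hi)
  if (size + 2L >= config$chrom_sizes[[ch]]) return(NULL)
  start <- sample.int(config$chrom_sizes[[ch]] - size - 1L, 1L)
  list(chrom = ch, start = start, end = start + size)
}

#' Plant truth deletions with population allele frequencies
#'
#' Places `n_truth` deletions realising the configured effect-class mix by
#' rejection sampling against [classify_deletions()] — the planted class of
#' every truth deletion is guaranteed to equal its classified class. Truth
#' deletions keep at least `min_gap` bp distance from one another so that
#' cross-sample clustering cannot merge distinct events. Per-population
#' allele frequencies are drawn from the configured zero-inflated Beta
#' model and per-sample genotypes from Hardy-Weinberg proportions at those
#' frequencies.
#'
#' @param annotation An `"sv_annotation"` from [simulate_annotation()].
#' @param config A [sim_config()] object.
#' @return A list of class `"sim_truth"`:
#'   * `deletions`: `data.frame(truth_id, chrom, start, end, class)` plus
#'     one planted-AF column per population;
#'   * `genotypes`: `data.frame(truth_id, sample_id, genotype)`.
#' @export
simulate_truth <- function(annotation, config) {
  set.seed(derive_seed(config$seed, "truth"))
  n <- config$n_truth
  classes <- sample(EFFECT_CLASSES, n, replace = TRUE,
                    prob = config$effect_mix)
  if (config$n_genes == 0L &&
      any(classes %in% c("CODING_EXON", "INTRONIC", "REGULATORY"))) {
    ds_stop("cannot realise genic effect classes with 0 genes")
  }
  placed <- data.frame(chrom = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(2000L)) {
      cand <- propose_interval(classes[i], annotation, config)
      if (is.null(cand) || cand$start < 1L) next
      if (cand$end + 1L > config$chrom_sizes[[cand$chrom]]) next
      same <- placed[placed$chrom == cand$chrom, , drop = FALSE]
      if (nrow(same) &&
          any(cand$start - config$min_gap < same$end &
              cand$end + config$min_gap > same$start)) next
      got <- as.character(classify_deletions(
        data.frame(chrom = cand$chrom, start = cand$start, end = cand$end),
        annotation, config$params$flank))
      if (got != classes[i]) next
      ok <- TRUE
      break
    }
    if (!ok) {
      ds_stop("could not place a ", classes[i],
              " deletion; relax the configuration (fewer/smaller deletions ",
              "or larger chromosomes)")
    }
    rows[[i]] <- data.frame(chrom = cand$chrom, start = cand$start,
                            end = cand$end, class = classes[i],
                            stringsAsFactors = FALSE)
    placed <- rbind(placed, rows[[i]][, c("chrom", "start", "end")])
  }
  dels <- do.call(rbind, rows)
  ord <- order(dels$chrom, dels$start)
  dels <- dels[ord, , drop = FALSE]
  dels <- cbind(truth_id = sprintf("T%04d", seq_len(n)), dels,
                stringsAsFactors = FALSE)
  rownames(dels) <- NULL

  pops <- names(config$populations)
  for (p in pops) {
    zero <- runif(n) < config$af_zero_prob
    af <- ifelse(zero, 0, rbeta(n, config$af_beta[1], config$af_beta[2]))
    dels[[paste0("af_", p)]] <- af
  }
  s2p <- sample_populations(config)
  geno <- do.call(rbind, lapply(names(s2p), function(s) {
    af <- dels[[paste0("af_", s2p[[s]])]]
    u <- runif(n)
    g <- ifelse(u < af^2, "DEL_DEL",
                ifelse(u < af^2 + 2 * af * (1 - af), "REF_DEL", "REF_REF"))
    data.frame(truth_id = dels$truth_id, sample_id = s, genotype = g,
               stringsAsFactors = FALSE)
  }))
  rownames(geno) <- NULL
  structure(list(deletions = dels, genotypes = geno), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("simulated truth: %d deletions (%s)\n", nrow(x$deletions),
              paste(sprintf("%s=%d", names(table(x$deletions$class)),
                            table(x$deletions$class)), collapse = ", ")))
  invisible(x)
}

# Realised per-population allele frequencies of the drawn genotypes
# (deleted alleles / 2 * samples), per truth deletion.
truth_realized_af <- function(truth, config) {
  s2p <- sample_populations(config)
  g <- truth$genotypes
  dose <- allele_dose(g$genotype)
  pop <- s2p[g$sample_id]
  out <- expand.grid(truth_id = truth$deletions$truth_id,
                     population = names(config$populations),
                     stringsAsFactors = FALSE)
  key <- paste(g$truth_id, pop)
  al <- tapply(dose, key, sum)
  okey <- paste(out$truth_id, out$population)
  out$af <- as.numeric(al[okey]) /
    (2 * as.integer(config$populations[out$population]))
  out[order(out$truth_id, out$population), , drop = FALSE]
}

#' Emit one caller's calls over the truth
#'
#' Simulates a caller observing the truth: every non-reference truth
#' genotype of a sample is emitted with probability `sensitivity`, its
#' breakpoints shifted independently by uniform integers in
#' `[-jitter_bp, jitter_bp]` (clamped to keep length >= 1), and its
#' genotype flipped between HET and HOM with `genotype_error_rate`.
#' False-positive calls are added per sample (Poisson count, log-normal
#' sizes) and placed by rejection sampling so that every false positive has
#' reciprocal overlap below the configured threshold with every truth
#' deletion and with every interval in `avoid` for the same sample — this
#' keeps ground-truth precision exactly computable. Output is deterministic
#' per `(seed, caller_id, sample)`.
#'
#' @param truth A `"sim_truth"` object.
#' @param profile A [caller_profile()].
#' @param config The [sim_config()].
#' @param avoid Optional call table (e.g. the other caller's output) whose
#'   per-sample false positives must also not be matched; used to make the
#'   two callers' false-positive sets non-overlapping by construction.
#' @return A call table in [read_deletions_vcf()] layout, with a logical
#'   `is_fp` column and the originating `truth_id` (`NA` for false
#'   positives).
#' @export
emit_caller_calls <- function(truth, profile, config, avoid = NULL) {
  samples <- config_samples(config)
  dels <- truth$deletions
  geno <- truth$genotypes
  ro_thr <- config$params$ro_threshold
  chroms <- names(config$chrom_sizes)
  out <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    s <- samples[si]
    set.seed(derive_seed(config$seed, "emit", profile$caller_id, s))
    g <- geno[geno$sample_id == s, , drop = FALSE]
    carrier <- g$genotype != "REF_REF"
    idx <- match(g$truth_id[carrier], dels$truth_id)
    emit <- runif(length(idx)) < profile$sensitivity
    idx <- idx[emit]
    gt <- g$genotype[carrier][emit]
    j <- profile$jitter_bp
    if (length(idx)) {
      ds <- if (j > 0) sample(-j:j, length(idx), replace = TRUE) else 0L
      de <- if (j > 0) sample(-j:j, length(idx), replace = TRUE) else 0L
      st <- pmax(1L, dels$start[idx] + ds)
      en <- pmax(st + 1L, dels$end[idx] + de)
      flip <- runif(length(idx)) < profile$genotype_error_rate
      gt[flip] <- ifelse(gt[flip] == "REF_DEL", "DEL_DEL", "REF_DEL")
      tp <- data.frame(chrom = dels$chrom[idx], start = st, end = en,
                       sample_id = s, caller_id = profile$caller_id,
                       genotype = gt,
                       qual = round(runif(length(idx), 30, 99), 1),
                       truth_id = dels$truth_id[idx], is_fp = FALSE,
                       stringsAsFactors = FALSE)
    } else {
      tp <- NULL
    }
    n_fp <- rpois(1L, profile$fp_per_sample)
    forbid <- dels[, c("chrom", "start", "end")]
    if (!is.null(avoid)) {
      av <- avoid[avoid$sample_id == s, c("chrom", "start", "end")]
      forbid <- rbind(forbid, av)
    }
    fps <- vector("list", n_fp)
    for (k in seq_len(n_fp)) {
      placedk <- FALSE
      for (try in seq_len(500L)) {
        size <- max(50L, as.integer(round(
          10^rnorm(1, profile$fp_size_log10_mean, profile$fp_size_log10_sd))))
        ch <- sample(chroms, 1L,
                     prob = config$chrom_sizes / sum(config$chrom_sizes))
        if (size + 2L >= config$chrom_sizes[[ch]]) next
        st <- sample.int(config$chrom_sizes[[ch]] - size - 1L, 1L)
        cand <- data.frame(chrom = ch, start = st, end = st + size)
        near <- forbid[forbid$chrom == ch &
                         forbid$start < cand$end & forbid$end > cand$start, ,
                       drop = FALSE]
        if (nrow(near) && any(reciprocal_overlap(
          cand[rep(1L, nrow(near)), ], near) >= ro_thr)) next
        placedk <- TRUE
        break
      }
      if (!placedk) {
        ds_stop("false-positive placement failed; lower fp_per_sample or ",
                "enlarge the genome")
      }
      fps[[k]] <- data.frame(chrom = cand$chrom, start = cand$start,
                             end = cand$end, sample_id = s,
                             caller_id = profile$caller_id,
                             genotype = sample(c("REF_DEL", "DEL_DEL"), 1L),
                             qual = round(runif(1, 30, 99), 1),
                             truth_id = NA_character_, is_fp = TRUE,
                             stringsAsFactors = FALSE)
      forbid <- rbind(forbid, fps[[k]][, c("chrom", "start", "end")])
    }
    out[[si]] <- rbind(tp, if (n_fp > 0) do.call(rbind, fps))
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(chrom = character(), start = integer(),
                      end = integer(), sample_id = character(),
                      caller_id = character(), genotype = character(),
                      qual = numeric(), truth_id = character(),
                      is_fp = logical(), stringsAsFactors = FALSE)
  }
  res <- res[order(res$sample_id, res$chrom, res$start, res$end), ,
             drop = FALSE]
  res$record_id <- sprintf("%s:%s:%d", res$caller_id, res$sample_id,
                           as.integer(stats::ave(seq_len(nrow(res)),
                                                 res$sample_id,
                                                 FUN = seq_along)))
  rownames(res) <- NULL
  res
}

#' Build a gene-set collection with one planted enriched set
#'
#' Creates `n_decoy_sets` gene sets drawn uniformly from the background and
#' one planted set whose members are drawn from `truth_genes` with
#' probability `set_truth_prob` — the positive control for the enrichment
#' stage.
#'
#' @param truth_genes Genes genuinely affected by deletions (the generator
#'   truth).
#' @param background All gene ids.
#' @param config A [sim_config()].
#' @return Named list of gene sets; the planted set is named
#'   `"planted_set"`.
#' @export
simulate_gene_sets <- function(truth_genes, background, config) {
  set.seed(derive_seed(config$seed, "gmt"))
  size <- min(config$set_size, length(background))
  sets <- lapply(seq_len(config$n_decoy_sets), function(i) {
    sample(background, size)
  })
  names(sets) <- sprintf("decoy_set_%02d", seq_len(config$n_decoy_sets))
  truth_pool <- intersect(truth_genes, background)
  n_truthy <- min(sum(runif(size) < config$set_truth_prob),
                  length(truth_pool))
  other_pool <- setdiff(background, truth_pool)
  sets$planted_set <- c(
    truth_pool[sample.int(length(truth_pool), n_truthy)],
    other_pool[sample.int(length(other_pool), size - n_truthy)])
  sets
}

#' Simulate a full cohort: annotation, truth, and two caller call sets
#'
#' Runs [simulate_annotation()], [simulate_truth()] and
#' [emit_caller_calls()] for both configured caller profiles. The second
#' caller's false positives are placed to avoid the first caller's
#' (per sample), so a false call can never survive the dual-caller
#' consensus — precision against truth is exactly 1 by construction.
#' When `dir` is given, all standard input files are written there:
#' `annotation.gff3`, per-sample per-caller VCFs under `vcf/`,
#' `gene_sets.gmt`, and truth tables under `truth/`.
#'
#' @param config A [sim_config()] object.
#' @param dir Optional output directory for the simulated input files.
#' @return A list of class `"sim_cohort"` with elements `annotation`,
#'   `truth`, `calls` (named list of two call tables), `gene_sets`,
#'   `config`, and (when written) `files`.
#' @export
simulate_cohort <- function(config, dir = NULL) {
  annotation <- simulate_annotation(config)
  truth <- simulate_truth(annotation, config)
  p1 <- config$profiles[[1]]; p2 <- config$profiles[[2]]
  calls1 <- emit_caller_calls(truth, p1, config)
  calls2 <- emit_caller_calls(truth, p2, config,
                              avoid = calls1[calls1$is_fp, , drop = FALSE])
  calls <- setNames(list(calls1, calls2),
                    c(p1$caller_id, p2$caller_id))
  tt <- truth_tables(truth, annotation, config)
  gene_sets <- simulate_gene_sets(tt$gene_catalog, pc_genes(annotation)$gene_id,
                                  config)
  out <- structure(list(annotation = annotation, truth = truth,
                        calls = calls, gene_sets = gene_sets,
                        config = config),
                   class = "sim_cohort")
  if (!is.null(dir)) {
    dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
    files <- list(gff3 = file.path(dir, "annotation.gff3"),
                  gmt = file.path(dir, "gene_sets.gmt"))
    write_gff3(annotation, files$gff3)
    write_gmt(gene_sets, files$gmt)
    files$vcf <- list()
    for (cl in names(calls)) {
      for (s in config_samples(config)) {
        path <- file.path(dir, "vcf", sprintf("%s.%s.vcf", s, cl))
        write_caller_vcf(calls[[cl]][calls[[cl]]$sample_id == s, , drop = FALSE],
                         path, s, contigs = config$chrom_sizes)
        files$vcf[[paste(s, cl, sep = ".")]] <- path
      }
    }
    write_tsv(truth$deletions, file.path(dir, "truth", "deletions.tsv"))
    write_tsv(truth$genotypes, file.path(dir, "truth", "genotypes.tsv"))
    write_tsv(data.frame(gene_id = tt$gene_catalog),
              file.path(dir, "truth", "gene_catalog.tsv"))
    out$files <- files
  }
  out
}

#' Expected pipeline results under noise-free conditions
#'
#' Computes, from the generator truth, what a perfectly sensitive,
#' jitter-free, error-free dual-caller pipeline must recover: the truth
#' deletions within the size gate that have at least one carrier (the
#' expected loci with their genotypes and realised per-population allele
#' frequencies), and the allele-frequency-filtered genic gene catalog.
#'
#' @param truth A `"sim_truth"` object.
#' @param annotation The matching annotation.
#' @param config The [sim_config()].
#' @return List with `loci` (truth deletions expected as loci, with
#'   realised AF columns), `genotypes` (their non-reference genotypes) and
#'   `gene_catalog` (character vector of gene ids).
#' @export
truth_tables <- function(truth, annotation, config) {
  params <- config$params
  dels <- truth$deletions
  len <- dels$end - dels$start
  in_range <- len >= params$min_len & len <= params$max_len
  raf <- truth_realized_af(truth, config)
  carriers <- tapply(raf$af, raf$truth_id, max)
  has_carrier <- carriers[dels$truth_id] > 0
  keep <- in_range & has_carrier
  loci <- dels[keep, , drop = FALSE]
  for (p in names(config$populations)) {
    v <- raf$af[raf$population == p]
    names(v) <- raf$truth_id[raf$population == p]
    loci[[paste0("raf_", p)]] <- unname(v[loci$truth_id])
  }
  geno <- truth$genotypes
  geno <- geno[geno$truth_id %in% loci$truth_id &
                 geno$genotype != "REF_REF", , drop = FALSE]
  # Gene catalog from truth loci above the AF gate.
  maxaf <- do.call(pmax, c(lapply(names(config$populations), function(p) {
    loci[[paste0("raf_", p)]]
  }), list(na.rm = TRUE)))
  gate <- loci[maxaf > params$af_threshold, , drop = FALSE]
  hits <- genes_hit(data.frame(locus_id = gate$truth_id,
                               chrom = gate$chrom, start = gate$start,
                               end = gate$end, stringsAsFactors = FALSE),
                    annotation, params$flank)
  catalog <- sort(unique(hits$gene_id[hits$contact %in% c("EXON", "INTRON")]))
  rownames(loci) <- NULL; rownames(geno) <- NULL
  list(loci = loci, genotypes = geno, gene_catalog = catalog)
}

#' Simulate marker alignment-hit tables against two assemblies
#'
#' Generates a marker universe with known mapping status against two
#' reference assemblies and tabular alignment hits for each: every mapped
#' marker gets one clear best hit (plus worse decoy hits), and a configured
#' fraction of markers multi-map with exactly tied hits so the ambiguity
#' flag is exercised. Defaults emulate a study-scale panel of 1124 markers
#' with a few percent of markers failing to map to either assembly.
#'
#' @param seed Integer seed.
#' @param n_markers Marker-universe size.
#' @param miss_a,miss_b Probability that a marker has no hit against
#'   assembly A / B (independent).
#' @param tie_prob Probability that a mapped marker's best hit is exactly
#'   tied between two subjects.
#' @param chrom_sizes Named chromosome sizes of the simulated assemblies.
#' @return List with `hits_a`, `hits_b` (hit tables), `markers` (the
#'   universe) and `mapped_a`, `mapped_b` (truth mapping flags).
#' @export
simulate_marker_hits <- function(seed = 1L, n_markers = 1124L,
                                 miss_a = 0.06, miss_b = 0.08,
                                 tie_prob = 0.02,
                                 chrom_sizes = c(chr1 = 40000000L,
                                                 chr2 = 40000000L)) {
  set.seed(derive_seed(seed, "markers"))
  markers <- sprintf("Am%04d", seq_len(n_markers))
  gen <- function(miss) {
    mapped <- runif(n_markers) >= miss
    rows <- lapply(which(mapped), function(i) {
      ch <- sample(names(chrom_sizes), 1L)
      len <- sample(60:90, 1L)
      sstart <- sample.int(chrom_sizes[[ch]] - len, 1L)
      minus <- runif(1) < 0.5
      ev <- 10^-runif(1, 20, 80)
      bit <- round(len * 1.9 + runif(1, -5, 5), 1)
      best <- data.frame(
        qseqid = markers[i], sseqid = ch, pident = round(runif(1, 92, 100), 2),
        length = len, mismatch = sample(0:3, 1L), gapopen = 0L,
        qstart = 1L, qend = len,
        sstart = if (minus) sstart + len - 1L else sstart,
        send = if (minus) sstart else sstart + len - 1L,
        evalue = ev, bitscore = bit, stringsAsFactors = FALSE)
      n_dec <- sample(0:3, 1L)
      dec <- NULL
      if (n_dec > 0) {
        dch <- sample(names(chrom_sizes), n_dec, replace = TRUE)
        dst <- vapply(dch, function(c2) sample.int(chrom_sizes[[c2]] - len, 1L),
                      integer(1))
        dec <- data.frame(
          qseqid = markers[i], sseqid = dch,
          pident = round(runif(n_dec, 80, 95), 2),
          length = pmax(30L, len - sample(5:30, n_dec, replace = TRUE)),
          mismatch = sample(3:10, n_dec, replace = TRUE), gapopen = 0L,
          qstart = 1L, qend = len, sstart = dst, send = dst + len - 1L,
          evalue = ev * 10^runif(n_dec, 3, 10),
          bitscore = bit - runif(n_dec, 10, 40), stringsAsFactors = FALSE)
      }
      tie <- NULL
      if (runif(1) < tie_prob) {
        tie <- best
        tie$sseqid <- setdiff(names(chrom_sizes), best$sseqid)[1]
      }
      rbind(best, dec, tie)
    })
    list(hits = do.call(rbind, rows), mapped = mapped)
  }
  a <- gen(miss_a); b <- gen(miss_b)
  rownames(a$hits) <- rownames(b$hits) <- NULL
  a$hits$marker_id <- a$hits$qseqid
  b$hits$marker_id <- b$hits$qseqid
  list(hits_a = a$hits, hits_b = b$hits, markers = markers,
       mapped_a = markers[a$mapped], mapped_b = markers[b$mapped])
}
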