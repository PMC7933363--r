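#' Filter deletion calls by size
#'
#' Keeps calls whose length (`end - start`) lies within the inclusive range
#' `[min_len, max_len]`, preserving input order. The number of removed calls
#' is reported via [message()].
#'
#' @param calls Interval table (e.g. from [read_deletions_vcf()]).
#' @param min_len,max_len Inclusive bounds in bp.
#' @return The filtered table.
#' @examples
#' x <- intervals("chr1", c(0, 0, 0, 0), c(499, 500, 100000, 100001))
#' nrow(size_filter(x, 500, 100000))  # 2
#' @export
size_filter <- function(calls, min_len = 500L, max_len = 100000L) {
  if (min_len > max_len) ds_stop("min_len must be <= max_len")
  validate_intervals(calls, "deletion call")
  len <- interval_length(calls)
  keep <- len >= min_len & len <= max_len
  if (any(!keep)) {
    ds_note(sprintf("size filter removed %d of %d call(s)",
                    sum(!keep), length(keep)))
  }
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Candidate same-chromosome overlapping pairs between two interval tables,
# as a data.frame(i, j, ro); only pairs with ro >= threshold are returned.
ro_pairs <- function(a, b, ro_threshold) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.frame(i = integer(), j = integer(), ro = numeric()))
  }
  hits <- suppressWarnings(GenomicRanges::findOverlaps(as_gr0(a), as_gr0(b)))
  i <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
  if (!length(i)) return(data.frame(i = integer(), j = integer(), ro = numeric()))
  ro <- reciprocal_overlap(a[i, c("chrom", "start", "end")],
                           b[j, c("chrom", "start", "end")])
  keep <- ro >= ro_threshold
  data.frame(i = i[keep], j = j[keep], ro = ro[keep])
}

#' Intersect two callers' deletion calls for one sample
#'
#' Implements the dual-caller consensus rule: a primary-caller deletion is
#' retained when at least one secondary-caller deletion on the same
#' chromosome matches it with reciprocal overlap at or above the threshold.
#' Matching is greedy one-to-one in descending reciprocal overlap, breaking
#' ties by smaller start-position difference, then smaller secondary start;
#' each secondary call supports at most one primary call. Consensus calls
#' carry the primary caller's coordinates and genotype (falling back to the
#' secondary genotype when the primary one is missing).
#'
#' @param primary,secondary Call tables for one sample from the two callers,
#'   already size filtered.
#' @param ro_threshold Reciprocal-overlap threshold (inclusive).
#' @return A `data.frame` with the primary call columns plus `matched_ro`,
#'   `caller_primary`, `caller_secondary`, `source_primary`,
#'   `source_secondary`.
#' @export
intersect_callsets <- function(primary, secondary, ro_threshold = 0.5) {
  validate_intervals(primary, "primary call")
  validate_intervals(secondary, "secondary call")
  for (df in list(primary, secondary)) {
    if (nrow(df) && length(unique(df$sample_id)) > 1L) {
      ds_stop("intersect_callsets expects calls from a single sample")
    }
  }
  sp <- unique(primary$sample_id); ss <- unique(secondary$sample_id)
  if (length(sp) && length(ss) && !identical(sp, ss)) {
    ds_stop("primary and secondary calls are from different samples")
  }
  out_cols <- function(p_idx, s_idx, ro) {
    res <- primary[p_idx, , drop = FALSE]
    res$matched_ro <- ro
    res$caller_primary <- if (nrow(res)) primary$caller_id[p_idx] else character(0)
    res$caller_secondary <- if (nrow(res)) secondary$caller_id[s_idx] else character(0)
    res$source_primary <- primary$record_id[p_idx]
    res$source_secondary <- secondary$record_id[s_idx]
    if (!is.null(res$genotype) && !is.null(secondary$genotype)) {
      miss <- res$genotype == "MISSING"
      res$genotype[miss] <- secondary$genotype[s_idx][miss]
    }
    rownames(res) <- NULL
    res
  }
  pairs <- ro_pairs(primary, secondary, ro_threshold)
  if (!nrow(pairs)) return(out_cols(integer(0), integer(0), numeric(0)))
  # Deterministic greedy order: best ro first; ties by |start difference|,
  # then secondary start, then primary start/record for full reproducibility.
  dstart <- abs(primary$start[pairs$i] - secondary$start[pairs$j])
  ord <- order(-pairs$ro, dstart, secondary$start[pairs$j],
               primary$start[pairs$i], primary$record_id[pairs$i],
               secondary$record_id[pairs$j])
  pairs <- pairs[ord, , drop = FALSE]
  used_p <- logical(nrow(primary)); used_s <- logical(nrow(secondary))
  take <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (!used_p[i] && !used_s[j]) {
      used_p[i] <- TRUE; used_s[j] <- TRUE; take[k] <- TRUE
    }
  }
  sel <- pairs[take, , drop = FALSE]
  keep_order <- order(sel$i)
  sel <- sel[keep_order, , drop = FALSE]
  out_cols(sel$i, sel$j, sel$ro)
}

# Union-find with path compression; used for single-linkage clustering.
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

#' Cluster consensus deletions across samples into loci
#'
#' Single-linkage clustering of consensus calls: two calls are linked when
#' their reciprocal overlap meets the threshold, and each connected
#' component becomes one deletion locus. The locus representative interval
#' is the component-wise lower median of member starts and ends. Allele
#' frequencies are computed per population from member genotypes: samples of
#' a population without a call at the locus count as homozygous reference,
#' and samples with missing genotypes are excluded from the denominator
#' (`AF = deleted alleles / (2 * samples with a defined genotype)`).
#'
#' @param consensus Consensus call table across samples (rows from
#'   [intersect_callsets()], concatenated).
#' @param sample_to_population Named character vector mapping every sample
#'   that had call data to its population; the names define the cohort used
#'   in allele-frequency denominators.
#' @param ro_threshold Reciprocal-overlap threshold for linkage.
#' @return An object of class `"deletion_loci"`: list with
#'   * `loci`: `data.frame(locus_id, chrom, start, end, n_members)`;
#'   * `genotypes`: `data.frame(locus_id, sample_id, genotype, matched_ro)`;
#'   * `af`: `data.frame(locus_id, population, af, n_called)`.
#' @export
cluster_loci <- function(consensus, sample_to_population, ro_threshold = 0.5) {
  validate_intervals(consensus, "consensus call")
  unknown <- setdiff(unique(consensus$sample_id), names(sample_to_population))
  if (length(unknown)) {
    ds_stop("sample(s) missing from population map: ",
            paste(unknown, collapse = ", "))
  }
  n <- nrow(consensus)
  parent <- seq_len(n)
  if (n > 1L) {
    pairs <- ro_pairs(consensus, consensus, ro_threshold)
    pairs <- pairs[pairs$i < pairs$j, , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      ri <- uf_find(parent, pairs$i[k]); rj <- uf_find(parent, pairs$j[k])
      if (ri != rj) parent[rj] <- ri
    }
  }
  comp <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  comp_ids <- unique(comp)
  # Order loci genomically by representative coordinates.
  reps <- do.call(rbind, lapply(comp_ids, function(cid) {
    m <- consensus[comp == cid, , drop = FALSE]
    data.frame(chrom = m$chrom[1],
               start = lower_median(m$start),
               end = lower_median(m$end),
               n_members = nrow(m), stringsAsFactors = FALSE)
  }))
  ord <- order(reps$chrom, reps$start, reps$end)
  reps <- reps[ord, , drop = FALSE]
  comp_ids <- comp_ids[ord]
  reps$locus_id <- sprintf("L%04d", seq_len(nrow(reps)))
  reps <- reps[, c("locus_id", "chrom", "start", "end", "n_members")]
  rownames(reps) <- NULL

  geno <- do.call(rbind, lapply(seq_along(comp_ids), function(li) {
    m <- consensus[comp == comp_ids[li], , drop = FALSE]
    # A sample can contribute several member calls to one locus; keep the
    # most severe genotype (DEL_DEL > REF_DEL > MISSING > REF_REF).
    sev <- c(DEL_DEL = 3L, REF_DEL = 2L, MISSING = 1L, REF_REF = 0L)
    m <- m[order(-sev[m$genotype]), , drop = FALSE]
    m <- m[!duplicated(m$sample_id), , drop = FALSE]
    data.frame(locus_id = reps$locus_id[li], sample_id = m$sample_id,
               genotype = m$genotype, matched_ro = m$matched_ro,
               stringsAsFactors = FALSE)
  }))
  if (is.null(geno)) {
    geno <- data.frame(locus_id = character(), sample_id = character(),
                       genotype = character(), matched_ro = numeric())
  }
  geno <- geno[order(geno$locus_id, geno$sample_id), , drop = FALSE]
  rownames(geno) <- NULL

  af <- locus_af(reps, geno, sample_to_population)
  structure(list(loci = reps, genotypes = geno, af = af),
            class = "deletion_loci",
            callers = unique(c(consensus$caller_primary,
                               consensus$caller_secondary)))
}

# Per-population allele frequencies for every locus. Absent samples count
# as REF_REF; MISSING genotypes drop out of the denominator.
locus_af <- function(reps, geno, sample_to_population) {
  pops <- sort(unique(sample_to_population))
  pop_sizes <- table(factor(sample_to_population, levels = pops))
  out <- expand.grid(locus_id = reps$locus_id, population = pops,
                     stringsAsFactors = FALSE)
  out <- out[order(out$locus_id, out$population), , drop = FALSE]
  dose <- allele_dose(geno$genotype)
  gpop <- sample_to_population[geno$sample_id]
  key <- paste(geno$locus_id, gpop)
  n_missing <- tapply(is.na(dose), key, sum)
  alleles <- tapply(dose, key, sum, na.rm = TRUE)
  okey <- paste(out$locus_id, out$population)
  nm <- ifelse(okey %in% names(n_missing), n_missing[okey], 0L)
  al <- ifelse(okey %in% names(alleles), alleles[okey], 0L)
  out$n_called <- as.integer(pop_sizes[out$population]) - as.integer(nm)
  out$af <- ifelse(out$n_called > 0L, al / (2 * out$n_called), NA_real_)
  rownames(out) <- NULL
  out[, c("locus_id", "population", "af", "n_called")]
}

#' @export
print.deletion_loci <- function(x, ...) {
  cat(sprintf("deletion loci: %d loci, %d member genotypes, %d population(s)\n",
              nrow(x$loci), nrow(x$genotypes),
              length(unique(x$af$population))))
  invisible(x)
}

# Wide per-locus table: coordinates, member count, one AF column per
# population. This is the loci TSV artifact.
loci_table <- function(loci) {
  af <- loci$af
  wide <- loci$loci
  for (p in sort(unique(af$population))) {
    v <- af$af[af$population == p]
    names(v) <- af$locus_id[af$population == p]
    wide[[paste0("af_", p)]] <- unname(v[wide$locus_id])
  }
  wide
}
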