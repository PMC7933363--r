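# Independent oracles used against the package implementations. These are
# deliberately naive (loops, brute force) and share no code with R/.

# Reciprocal overlap recomputed from first principles.
oracle_ro <- function(c1, s1, e1, c2, s2, e2) {
  if (c1 != c2) return(0)
  ov <- max(0, min(e1, e2) - max(s1, s2))
  min(ov / (e1 - s1), ov / (e2 - s2))
}

# O(n^2) greedy one-to-one matcher over all primary x secondary pairs,
# descending ro, ties by |start difference|, secondary start, then primary
# start and record ids.
oracle_intersect <- function(primary, secondary, thr = 0.5) {
  np <- nrow(primary); ns <- nrow(secondary)
  if (np == 0L || ns == 0L) return(integer(0))
  pr <- list()
  for (i in seq_len(np)) for (j in seq_len(ns)) {
    ro <- oracle_ro(primary$chrom[i], primary$start[i], primary$end[i],
                    secondary$chrom[j], secondary$start[j], secondary$end[j])
    if (ro >= thr) pr[[length(pr) + 1L]] <- c(i = i, j = j, ro = ro)
  }
  if (!length(pr)) return(integer(0))
  pm <- do.call(rbind, pr)
  ord <- order(-pm[, "ro"],
               abs(primary$start[pm[, "i"]] - secondary$start[pm[, "j"]]),
               secondary$start[pm[, "j"]], primary$start[pm[, "i"]],
               primary$record_id[pm[, "i"]], secondary$record_id[pm[, "j"]])
  pm <- pm[ord, , drop = FALSE]
  used_p <- rep(FALSE, np); used_s <- rep(FALSE, ns); taken <- integer(0)
  for (r in seq_len(nrow(pm))) {
    i <- pm[r, "i"]; j <- pm[r, "j"]
    if (!used_p[i] && !used_s[j]) {
      used_p[i] <- TRUE; used_s[j] <- TRUE
      taken <- c(taken, i)
    }
  }
  sort(taken)
}

# Transitive closure of the ro-threshold adjacency matrix: cluster labels
# by repeated boolean matrix multiplication.
oracle_components <- function(df, thr = 0.5) {
  n <- nrow(df)
  adj <- diag(n) > 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j &&
        oracle_ro(df$chrom[i], df$start[i], df$end[i],
                  df$chrom[j], df$start[j], df$end[j]) >= thr) {
      adj[i, j] <- TRUE
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0 | adj
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  # label = smallest reachable index
  apply(adj, 1L, function(r) min(which(r)))
}

# Exact upper-tail hypergeometric by direct enumeration with choose().
oracle_hyper_sf <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  if (k <= 0) return(1)
  j <- k:hi
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Random deletion-call table on a few chromosomes.
random_calls <- function(n, chroms = c("chr1", "chr2", "chr3"),
                         span = 1e6, len_range = c(100, 5000),
                         sample_id = "s1", caller_id = "x") {
  len <- as.integer(runif(n, len_range[1], len_range[2]))
  start <- as.integer(runif(n, 1, span))
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len,
             sample_id = sample_id, caller_id = caller_id,
             genotype = sample(c("REF_DEL", "DEL_DEL"), n, replace = TRUE),
             qual = 50, record_id = sprintf("%s%04d", caller_id, seq_len(n)),
             stringsAsFactors = FALSE)
}
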