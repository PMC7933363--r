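#' Hypergeometric upper-tail probability
#'
#' Over-representation p-value: `P(X >= k)` for `X ~ Hypergeometric(N, K,
#' n)` — drawing `n` genes from a background of `N` of which `K` belong to
#' the set. Computed by summing the probability mass in log space for
#' numerical stability; `k = 0` returns exactly 1 and `k > min(K, n)`
#' returns exactly 0.
#'
#' @param k Number of query genes in the set (may be a vector).
#' @param K Set size within the background.
#' @param n Query size within the background.
#' @param N Background size.
#' @return Numeric vector of upper-tail probabilities in \[0, 1\].
#' @examples
#' hypergeom_sf(3, 5, 4, 10)  # 55/210
#' @export
hypergeom_sf <- function(k, K, n, N) {
  if (length(K) != 1L || length(n) != 1L || length(N) != 1L) {
    ds_stop("K, n, N must be scalars")
  }
  if (K < 0 || K > N || n < 0 || n > N || any(k < 0)) {
    ds_stop("require 0 <= K <= N, 0 <= n <= N, k >= 0")
  }
  vapply(k, function(ki) {
    hi <- min(K, n)
    if (ki == 0) return(1)
    if (ki > hi) return(0)
    j <- ki:hi
    lp <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
    m <- max(lp)
    min(1, exp(m + log(sum(exp(lp - m)))))
  }, numeric(1))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up false-discovery-rate adjustment: with `m` p-values sorted
#' ascending, `q_(i) = min_{j >= i} (m * p_(j) / j)`, capped at 1 and
#' returned in the original input order. Applying the adjustment twice is a
#' no-op.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values in input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    ds_stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p)
  q <- pmin(1, rev(cummin(rev(m * p[ord] / seq_len(m)))))
  q[order(ord)]
}

#' Gene-set over-representation test
#'
#' Tests each gene set for over-representation of the query genes within a
#' background universe using [hypergeom_sf()], adjusting across the tested
#' sets with [bh_adjust()]. Query genes outside the background are dropped
#' with a warning; set members are intersected with the background, and
#' sets left empty are not tested.
#'
#' @param query Character vector of query gene ids (e.g. the deletion gene
#'   catalog).
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param background Character vector: the gene universe, e.g. all
#'   protein-coding genes of the annotation.
#' @param alpha Significance level applied to adjusted q-values.
#' @return `data.frame(set_name, k, K, n, N, p_value, q_value, significant)`
#'   sorted by q-value, then p-value, then set name.
#' @export
enrich_sets <- function(query, gene_sets, background, alpha = 0.05) {
  background <- unique(background)
  if (length(background) == 0L) ds_stop("empty background")
  query <- unique(query)
  outside <- setdiff(query, background)
  if (length(outside)) {
    warning(sprintf("%d query gene(s) outside the background dropped",
                    length(outside)))
    query <- intersect(query, background)
  }
  sets <- lapply(gene_sets, intersect, background)
  keep <- vapply(sets, length, integer(1)) >= 1L
  sets <- sets[keep]
  N <- length(background); n <- length(query)
  out <- data.frame(
    set_name = names(sets),
    k = vapply(sets, function(s) length(intersect(s, query)), integer(1)),
    K = vapply(sets, length, integer(1)),
    n = n, N = N, stringsAsFactors = FALSE)
  out$p_value <- vapply(seq_len(nrow(out)), function(i) {
    hypergeom_sf(out$k[i], out$K[i], out$n[i], out$N[i])
  }, numeric(1))
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$q_value < alpha
  out <- out[order(out$q_value, out$p_value, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
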