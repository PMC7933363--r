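test_that("reciprocal overlap matches direct arithmetic and is symmetric", {
  a <- intervals("chr1", 100, 200)
  expect_equal(reciprocal_overlap(a, a), 1.0)
  expect_equal(reciprocal_overlap(a, intervals("chr1", 150, 250)), 0.5)
  expect_equal(reciprocal_overlap(a, intervals("chr1", 300, 400)), 0.0)
  expect_equal(reciprocal_overlap(a, intervals("chr2", 100, 200)), 0.0)

  set.seed(101)
  x <- random_calls(200); y <- random_calls(200)
  expect_equal(reciprocal_overlap(x, y), reciprocal_overlap(y, x))
  expect_true(all(reciprocal_overlap(x, y) >= 0 &
                    reciprocal_overlap(x, y) <= 1))
})

test_that("size filter keeps the closed range [500, 100000]", {
  x <- intervals("chr1", rep(0L, 4), c(499L, 500L, 100000L, 100001L))
  kept <- suppressMessages(size_filter(x, 500, 100000))
  expect_equal(kept$end, c(500L, 100000L))
  expect_equal(nrow(size_filter(x[0, ], 500, 100000)), 0L)
  expect_equal(size_filter(x, 1, 1e9), x, ignore_attr = TRUE)
})

test_that("caller intersection keeps matches at the threshold and drops below it", {
  p <- random_calls(1, caller_id = "manta")
  p$start <- 1000L; p$end <- 2000L; p$chrom <- "chr1"
  s <- p; s$caller_id <- "lumpy"; s$record_id <- "y0001"
  s$start <- 1200L; s$end <- 2200L      # ro = 0.8
  cons <- intersect_callsets(p, s, 0.5)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$matched_ro, 0.8)
  expect_equal(cons$start, 1000L)       # primary coordinates kept
  s$start <- 1510L; s$end <- 2510L      # ro = 490/1000 < 0.5
  expect_equal(nrow(intersect_callsets(p, s, 0.5)), 0L)
  s$start <- 1500L; s$end <- 2500L      # ro exactly 0.5 -> kept (inclusive)
  expect_equal(nrow(intersect_callsets(p, s, 0.5)), 1L)
})

test_that("intersection equals the all-pairs brute-force matcher on random instances", {
  set.seed(2024)
  for (rep in 1:25) {
    p <- random_calls(sample(20:120, 1), caller_id = "a")
    s <- random_calls(sample(20:120, 1), caller_id = "b")
    got <- intersect_callsets(p, s, 0.5)
    want <- oracle_intersect(p, s, 0.5)
    expect_equal(got$record_id, p$record_id[want])
    expect_lte(nrow(got), min(nrow(p), nrow(s)))
  }
})

test_that("intersection is invariant to input row order", {
  set.seed(7)
  p <- random_calls(80, caller_id = "a")
  s <- random_calls(80, caller_id = "b")
  base <- intersect_callsets(p, s, 0.5)
  perm <- intersect_callsets(p[sample(nrow(p)), ], s[sample(nrow(s)), ], 0.5)
  expect_equal(base[order(base$record_id), ], perm[order(perm$record_id), ],
               ignore_attr = TRUE)
})

test_that("mixed samples in one callset are a hard error", {
  p <- random_calls(2); p$sample_id <- c("s1", "s2")
  expect_error(intersect_callsets(p, random_calls(2)), "single sample")
})

test_that("genotype falls back to the secondary caller when the primary is missing", {
  p <- random_calls(1, caller_id = "a"); p$genotype <- "MISSING"
  s <- p; s$caller_id <- "b"; s$genotype <- "DEL_DEL"; s$record_id <- "b1"
  expect_equal(intersect_callsets(p, s, 0.5)$genotype, "DEL_DEL")
})

make_consensus <- function(chrom, start, end, sample_id,
                           genotype = "REF_DEL") {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             sample_id = sample_id, caller_id = "a", genotype = genotype,
             qual = 50, record_id = sprintf("r%03d", seq_along(start)),
             matched_ro = 1, caller_primary = "a", caller_secondary = "b",
             stringsAsFactors = FALSE)
}

test_that("identical deletions in several samples form one locus; disjoint calls stay apart", {
  s2p <- c(s1 = "P", s2 = "P", s3 = "Q")
  cons <- make_consensus("chr1", c(100, 100, 100), c(600, 600, 600),
                         c("s1", "s2", "s3"))
  loci <- cluster_loci(cons, s2p)
  expect_equal(nrow(loci$loci), 1L)
  expect_equal(loci$loci$n_members, 3L)
  cons2 <- make_consensus("chr1", c(100, 5000), c(600, 5500), c("s1", "s2"))
  expect_equal(nrow(cluster_loci(cons2, s2p)$loci), 2L)
})

test_that("single-linkage chains merge even when the ends barely overlap", {
  # a-b ro 0.6, b-c ro 0.6, a-c ro ~0.3: one locus by transitivity
  s2p <- c(s1 = "P", s2 = "P", s3 = "P")
  cons <- make_consensus("chr1", c(1000, 1400, 1800), c(2000, 2400, 2800),
                         c("s1", "s2", "s3"))
  expect_equal(oracle_ro("chr1", 1000, 2000, "chr1", 1400, 2400), 0.6)
  expect_equal(oracle_ro("chr1", 1000, 2000, "chr1", 1800, 2800), 0.2)
  loci <- cluster_loci(cons, s2p)
  expect_equal(nrow(loci$loci), 1L)
  # representative = lower median of member coordinates
  expect_equal(loci$loci$start, 1400L)
  expect_equal(loci$loci$end, 2400L)
})

test_that("clustering matches the transitive-closure oracle and partitions the input", {
  set.seed(99)
  s2p <- setNames(rep(c("P", "Q"), 5), paste0("s", 1:10))
  for (rep in 1:10) {
    cons <- random_calls(60, span = 2e5)
    cons$sample_id <- sample(names(s2p), 60, replace = TRUE)
    cons$matched_ro <- 1
    cons$caller_primary <- "a"; cons$caller_secondary <- "b"
    loci <- cluster_loci(cons, s2p)
    want <- oracle_components(cons, 0.5)
    expect_equal(nrow(loci$loci), length(unique(want)))
    expect_equal(sum(loci$loci$n_members), nrow(cons))  # partition
  }
})

test_that("population allele frequencies use called samples and implicit REF_REF", {
  s2p <- c(s1 = "P", s2 = "P", s3 = "P", s4 = "Q")
  cons <- make_consensus("chr1", c(100, 100), c(600, 600), c("s1", "s2"),
                         genotype = c("REF_DEL", "DEL_DEL"))
  loci <- cluster_loci(cons, s2p)
  af <- loci$af
  # P: (1 + 2) alleles over 2*3 (s3 counts as REF_REF); Q: 0 over 2*1
  expect_equal(af$af[af$population == "P"], 0.5)
  expect_equal(af$af[af$population == "Q"], 0)
  # missing genotypes leave the denominator
  cons$genotype <- c("REF_DEL", "MISSING")
  af2 <- cluster_loci(cons, s2p)$af
  expect_equal(af2$af[af2$population == "P"], 1 / 4)
  expect_equal(af2$n_called[af2$population == "P"], 2L)
  expect_error(cluster_loci(cons, c(s1 = "P")), "population map")
})
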