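test_that("the generator is fully deterministic given the config seed", {
  cfg <- small_config(77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth, b$truth)
  expect_identical(a$calls, b$calls)
  expect_identical(a$gene_sets, b$gene_sets)
  # byte-identical files too
  d1 <- tempfile(); d2 <- tempfile()
  delscan:::write_gff3(a$annotation, d1)
  delscan:::write_gff3(b$annotation, d2)
  expect_identical(readLines(d1), readLines(d2))
  # a different seed changes the cohort
  expect_false(identical(simulate_cohort(small_config(78))$truth, a$truth))
})

test_that("planted effect classes agree with the classifier by construction", {
  cfg <- small_config(19)
  ann <- simulate_annotation(cfg)
  truth <- simulate_truth(ann, cfg)
  got <- classify_deletions(truth$deletions, ann, cfg$params$flank)
  expect_equal(as.character(got), truth$deletions$class)
  # the configured class mix is roughly realised
  expect_gt(min(table(truth$deletions$class)), 0)
})

test_that("truth deletions keep their distance and populations with AF 0 have no carriers", {
  cfg <- small_config(29)
  ann <- simulate_annotation(cfg)
  truth <- simulate_truth(ann, cfg)
  d <- truth$deletions
  for (ch in unique(d$chrom)) {
    x <- d[d$chrom == ch, ]
    x <- x[order(x$start), ]
    if (nrow(x) > 1) {
      expect_true(all(x$start[-1] - x$end[-nrow(x)] >= cfg$min_gap))
    }
  }
  s2p <- sample_populations(cfg)
  for (p in names(cfg$populations)) {
    zero_ids <- d$truth_id[d[[paste0("af_", p)]] == 0]
    g <- truth$genotypes
    carriers <- g[g$truth_id %in% zero_ids &
                    s2p[g$sample_id] == p & g$genotype != "REF_REF", ]
    expect_equal(nrow(carriers), 0L)
  }
})

test_that("genotype draws are Hardy-Weinberg consistent in aggregate", {
  cfg <- small_config(47)
  ann <- simulate_annotation(cfg)
  truth <- simulate_truth(ann, cfg)
  s2p <- sample_populations(cfg)
  g <- truth$genotypes
  d <- truth$deletions
  # pooled z-test: total deleted alleles vs sum of 2*af over all
  # (deletion, sample) pairs
  af <- unlist(lapply(names(s2p), function(s) d[[paste0("af_", s2p[[s]])]]))
  # order genotypes to match the af layout (sample block, then truth row)
  g2 <- g[order(match(g$sample_id, names(s2p)), match(g$truth_id, d$truth_id)), ]
  dose <- delscan:::allele_dose(g2$genotype)
  mu <- sum(2 * af)
  v <- sum(2 * af * (1 - af))
  z <- (sum(dose) - mu) / sqrt(v)
  expect_lt(abs(z), 4)
})

test_that("a noise-free caller reproduces the truth genotypes one-to-one", {
  cfg <- small_config(3, profiles = noisefree_profiles())
  ann <- simulate_annotation(cfg)
  truth <- simulate_truth(ann, cfg)
  calls <- emit_caller_calls(truth, cfg$profiles[[1]], cfg)
  carriers <- truth$genotypes[truth$genotypes$genotype != "REF_REF", ]
  expect_equal(nrow(calls), nrow(carriers))
  key <- function(t, s) paste(t, s)
  expect_setequal(key(calls$truth_id, calls$sample_id),
                  key(carriers$truth_id, carriers$sample_id))
  m <- match(key(calls$truth_id, calls$sample_id),
             key(carriers$truth_id, carriers$sample_id))
  expect_equal(calls$genotype, carriers$genotype[m])
  # exact truth intervals at jitter 0
  ti <- match(calls$truth_id, truth$deletions$truth_id)
  expect_equal(calls$start, truth$deletions$start[ti])
  expect_equal(calls$end, truth$deletions$end[ti])
})

test_that("breakpoint jitter of 50 bp cannot push a filtered call below the overlap threshold", {
  cfg <- small_config(9)  # default profiles: jitter 50
  ann <- simulate_annotation(cfg)
  truth <- simulate_truth(ann, cfg)
  calls <- emit_caller_calls(truth, cfg$profiles[[2]], cfg)
  tp <- calls[!calls$is_fp, ]
  ti <- match(tp$truth_id, truth$deletions$truth_id)
  ro <- reciprocal_overlap(tp[, c("chrom", "start", "end")],
                           truth$deletions[ti, c("chrom", "start", "end")])
  len <- truth$deletions$end[ti] - truth$deletions$start[ti]
  expect_true(all(ro[len >= 500] >= 0.5))
  # worst case arithmetic: a 500 bp deletion shrunk by 50 at both ends
  expect_gt(oracle_ro("c", 0, 500, "c", 50, 450), 0.5)
})

test_that("false positives never match truth or the other caller's false positives", {
  cfg <- small_config(21)
  co <- simulate_cohort(cfg)
  truth <- co$truth$deletions
  for (cl in names(co$calls)) {
    fp <- co$calls[[cl]][co$calls[[cl]]$is_fp, ]
    for (i in sample(nrow(fp), min(40, nrow(fp)))) {
      ro <- reciprocal_overlap(fp[i, c("chrom", "start", "end")],
                               truth[, c("chrom", "start", "end")])
      expect_lt(max(ro), 0.5)
    }
  }
  # cross-caller, same sample
  f1 <- co$calls[[1]][co$calls[[1]]$is_fp, ]
  f2 <- co$calls[[2]][co$calls[[2]]$is_fp, ]
  for (s in unique(f1$sample_id)[1:4]) {
    a <- f1[f1$sample_id == s, ]; b <- f2[f2$sample_id == s, ]
    if (!nrow(a) || !nrow(b)) next
    for (i in seq_len(nrow(a))) {
      ro <- reciprocal_overlap(a[i, c("chrom", "start", "end")],
                               b[, c("chrom", "start", "end")])
      expect_lt(max(ro), 0.5)
    }
  }
})
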