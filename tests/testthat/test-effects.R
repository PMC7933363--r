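test_that("effect classes follow the exon > intron > flank > intergenic priority", {
  ann <- toy_annotation()
  cls <- function(start, end) {
    as.character(classify_deletions(intervals("chr1", start, end), ann, 1000L))
  }
  expect_equal(cls(10499, 10600), "CODING_EXON")   # 1 bp of exon 1
  expect_equal(cls(10500, 14999), "INTRONIC")      # strictly between exons
  expect_equal(cls(9000, 9500), "REGULATORY")      # upstream flank
  expect_equal(cls(20500, 20900), "REGULATORY")    # downstream flank
  expect_equal(cls(5000, 6000), "INTERGENIC")
  # spans exon of geneA and flank of geneB -> exon wins
  expect_equal(cls(19000, 49500), "CODING_EXON")
  # non-protein-coding genes play no role
  expect_equal(as.character(classify_deletions(
    intervals("chr2", 1000, 2000), ann, 1000L)), "INTERGENIC")
})

test_that("the regulatory flank boundary sits exactly at the configured distance", {
  ann <- toy_annotation()
  cls <- function(start, end) {
    as.character(classify_deletions(intervals("chr1", start, end), ann, 1000L))
  }
  # geneA span starts at 10000; deletion END is 0-based-exclusive, so a
  # deletion ending d bp before the span overlaps the flank iff d <= 999.
  expect_equal(cls(8000, 10000 - 999), "REGULATORY")
  expect_equal(cls(8000, 10000 - 1001), "INTERGENIC")
  # enlarging the flank is monotone: REGULATORY never becomes INTERGENIC
  q <- intervals("chr1", 8000, 10000 - 999)
  expect_equal(as.character(classify_deletions(q, ann, 2000L)), "REGULATORY")
})

test_that("unknown chromosomes classify as intergenic with a notice", {
  ann <- toy_annotation()
  expect_message(
    cls <- classify_deletions(intervals("chrZ", 0, 100), ann, 1000L),
    "absent")
  expect_equal(as.character(cls), "INTERGENIC")
})

test_that("classification is an exhaustive partition", {
  cfg <- small_config(13)
  ann <- simulate_annotation(cfg)
  set.seed(13)
  q <- random_calls(200, chroms = c("chr1", "chr2"), span = 7e6)
  cls <- classify_deletions(q, ann, 1000L)
  expect_equal(sum(table(cls)), 200L)
  expect_false(anyNA(cls))
})

test_that("genes_hit reports the strongest per-gene contact", {
  ann <- toy_annotation()
  # one interval over an exon of geneA through the flank of geneB
  loci <- intervals("chr1", 19000, 49500, locus_id = "L1")
  hits <- genes_hit(loci, ann, 1000L)
  expect_equal(hits$gene_id, c("geneA", "geneB"))
  expect_equal(hits$contact, c("EXON", "FLANK"))
  # gene desert
  expect_equal(nrow(genes_hit(intervals("chr1", 100, 200, locus_id = "L2"),
                              ann, 1000L)), 0L)
  # intron-only contact
  expect_equal(genes_hit(intervals("chr1", 11000, 12000, locus_id = "L3"),
                         ann, 1000L)$contact, "INTRON")
})

test_that("genes_hit equals a brute-force per-gene scan on random loci", {
  cfg <- small_config(31)
  ann <- simulate_annotation(cfg)
  set.seed(31)
  q <- random_calls(100, chroms = c("chr1", "chr2"), span = 7e6)
  q$locus_id <- sprintf("L%03d", seq_len(nrow(q)))
  hits <- genes_hit(q, ann, 1000L)
  genes <- ann$genes[ann$genes$biotype == "protein_coding", ]
  for (i in sample(nrow(q), 20)) {
    want <- character(0)
    for (g in seq_len(nrow(genes))) {
      if (genes$chrom[g] == q$chrom[i] &&
          q$start[i] < genes$end[g] + 1000 &&
          q$end[i] > genes$start[g] - 1000) {
        want <- c(want, genes$gene_id[g])
      }
    }
    expect_setequal(hits$gene_id[hits$locus_id == q$locus_id[i]], want)
  }
})

toy_loci <- function(af_values) {
  # two loci: one in geneA's intron, one in the desert, with given max AFs
  loci <- data.frame(locus_id = c("L1", "L2"), chrom = "chr1",
                     start = c(11000L, 100L), end = c(12000L, 200L),
                     n_members = 1L, stringsAsFactors = FALSE)
  af <- data.frame(locus_id = rep(c("L1", "L2"), each = 1),
                   population = "P", af = af_values, n_called = 4L,
                   stringsAsFactors = FALSE)
  structure(list(loci = loci,
                 genotypes = data.frame(locus_id = c("L1", "L2"),
                                        sample_id = "s1",
                                        genotype = "REF_DEL",
                                        matched_ro = 1),
                 af = af), class = "deletion_loci")
}

test_that("the gene catalog applies a strict allele-frequency gate", {
  ann <- toy_annotation()
  expect_equal(nrow(gene_catalog(toy_loci(c(0.05, 0.5)), ann)$genic), 0L)
  cat2 <- gene_catalog(toy_loci(c(0.06, 0.5)), ann)
  expect_equal(cat2$genic$gene_id, "geneA")
  expect_equal(cat2$genic$contact, "INTRON")
  expect_equal(cat2$genic$best_af, 0.06)
  # a lower threshold can only grow the catalog
  cat0 <- gene_catalog(toy_loci(c(0.06, 0.5)), ann, af_threshold = 0)
  expect_true(all(cat2$genic$gene_id %in% cat0$genic$gene_id))
  # threshold at/above every AF empties it
  expect_equal(nrow(gene_catalog(toy_loci(c(0.06, 0.5)), ann,
                                 af_threshold = 0.99)$genic), 0L)
})

test_that("pooled AF mode gates on alleles pooled across populations", {
  ann <- toy_annotation()
  loci <- toy_loci(c(0.10, 0.5))
  # second population without the deletion halves the pooled frequency
  loci$af <- rbind(loci$af,
                   data.frame(locus_id = c("L1", "L2"), population = "Q",
                              af = 0, n_called = 4L))
  expect_equal(gene_catalog(loci, ann)$genic$gene_id, "geneA")  # max = 0.10
  # pooled: (0.10 * 8 + 0) / 16 = 0.05, excluded by the strict gate
  expect_equal(nrow(gene_catalog(loci, ann, af_mode = "pooled")$genic), 0L)
})

test_that("flank-only gene contacts land in the regulatory catalog", {
  ann <- toy_annotation()
  loci <- toy_loci(c(0.2, 0.2))
  loci$loci$start <- c(9000L, 100L); loci$loci$end <- c(9500L, 200L)
  cat <- gene_catalog(loci, ann)
  expect_equal(nrow(cat$genic), 0L)
  expect_equal(cat$regulatory$gene_id, "geneA")
  expect_equal(cat$regulatory$contact, "FLANK")
})

test_that("effect counts sum to the number of classified loci", {
  cfg <- small_config(55, profiles = noisefree_profiles())
  run <- run_pipeline(cfg, tempfile(), io = "memory")
  counts <- run$effects
  total <- counts[counts$population == "total", -1]
  expect_equal(sum(unlist(total)), nrow(run$loci$loci))
})
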