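write_vcf_lines <- function(records, samples = "s1", path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"l\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

test_that("symbolic and explicit deletion records convert to 0-based half-open spans", {
  p <- write_vcf_lines(c(
    "chr1\t1000\td1\tN\t<DEL>\t50\tPASS\tSVTYPE=DEL;END=1500;SVLEN=-500\tGT\t0/1",
    "chr1\t100\td2\tACGTA\tA\t99\tPASS\t.\tGT\t1|1"))
  calls <- suppressMessages(read_deletions_vcf(p, "manta"))
  # record order follows the file: symbolic d1, then explicit d2
  expect_equal(calls$start, c(1000L, 100L))
  expect_equal(calls$end, c(1500L, 104L))
  expect_equal(calls$end - calls$start, c(500L, 4L))
  expect_equal(calls$genotype, c("REF_DEL", "DEL_DEL"))
  expect_equal(calls$caller_id, rep("manta", 2))
})

test_that("non-deletion records are skipped with a tally", {
  p <- write_vcf_lines(c(
    "chr1\t1000\td1\tN\t<DEL>\t50\tPASS\tSVTYPE=DEL;END=1500\tGT\t0/1",
    "chr1\t3000\td2\tN\t<DUP>\t50\tPASS\tSVTYPE=DUP;END=4000\tGT\t0/1",
    "chr1\t9000\td3\tN\t<DEL>\t50\tPASS\tSVTYPE=DEL;END=9400\tGT\t1/1"))
  calls <- suppressMessages(read_deletions_vcf(p, "manta"))
  expect_equal(nrow(calls), 2L)
  expect_equal(attr(calls, "tally")[["non_del"]], 1L)
})

test_that("malformed records are rejected and counted, END wins over SVLEN", {
  p <- write_vcf_lines(c(
    "chr1\t1000\tok\tN\t<DEL>\t50\tPASS\tSVTYPE=DEL;END=1500;SVLEN=-999\tGT\t0/1",
    "chr1\t2000\tbad1\tN\t<DEL>\t50\tPASS\tSVTYPE=DEL;END=1500\tGT\t0/1",
    "chr1\t5000\tbad2\tN\t<DEL>,<DUP>\t50\tPASS\tSVTYPE=DEL;END=5500\tGT\t0/1",
    "chr1\t6000\tbad3\tN\t<DEL>\t50\tPASS\tSVTYPE=DEL;END=6500\tGT\t0/2"))
  calls <- suppressMessages(read_deletions_vcf(p, "manta"))
  expect_equal(calls$record_id, "ok")
  expect_equal(calls$end, 1500L)  # END, not POS + |SVLEN|
  tally <- attr(calls, "tally")
  expect_equal(tally[["bad_coord"]], 1L)
  expect_equal(tally[["multiallelic"]], 1L)
  expect_equal(tally[["bad_gt"]], 1L)
  expect_equal(tally[["end_svlen_conflict"]], 1L)
})

test_that("missing GT yields MISSING genotype in single-sample files", {
  p <- write_vcf_lines(
    "chr1\t1000\td1\tN\t<DEL>\t50\tPASS\tSVTYPE=DEL;END=1500\tGT\t.")
  calls <- suppressMessages(read_deletions_vcf(p, "manta"))
  expect_equal(calls$genotype, "MISSING")
})

test_that("GFF3 coordinates convert to 0-based half-open and indexes cover all chromosomes", {
  p <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t10\t100\t.\t+\t.\tID=g1;gene_biotype=protein_coding",
    "chr1\tsrc\texon\t10\t40\t.\t+\t.\tID=g1.e1;Parent=g1",
    "chr2\tsrc\tgene\t200\t300\t.\t-\t.\tID=g2;gene_biotype=protein_coding",
    "chr2\tsrc\tmRNA\t200\t300\t.\t-\t.\tID=g2.t1;Parent=g2",
    "chr2\tsrc\texon\t200\t250\t.\t-\t.\tID=g2.e1;Parent=g2.t1"), p)
  ann <- read_gff3(p)
  g1 <- ann$genes[ann$genes$gene_id == "g1", ]
  expect_equal(c(g1$start, g1$end), c(9L, 100L))
  e1 <- ann$exons[ann$exons$gene_id == "g1", ]
  expect_equal(c(e1$start, e1$end), c(9L, 40L))
  # exon Parent resolved through the transcript level
  expect_equal(ann$exons$gene_id[ann$exons$chrom == "chr2"], "g2")
  expect_setequal(unique(ann$genes$chrom), c("chr1", "chr2"))
})

test_that("orphan exons and exons outside the gene span are hard errors", {
  p <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t10\t100\t.\t+\t.\tID=g1",
    "chr1\tsrc\texon\t10\t40\t.\t+\t.\tID=e1;Parent=ghost"), p)
  expect_error(read_gff3(p), "orphan exon")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t10\t100\t.\t+\t.\tID=g1",
    "chr1\tsrc\texon\t10\t140\t.\t+\t.\tID=e1;Parent=g1"), p)
  expect_error(read_gff3(p), "outside gene span")
})

test_that("caller VCF and consensus VCF round-trip intervals and genotypes", {
  calls <- random_calls(5, sample_id = "s1", caller_id = "manta")
  p <- tempfile(fileext = ".vcf")
  delscan:::write_caller_vcf(calls, p, "s1")
  back <- suppressMessages(read_deletions_vcf(p, "manta"))
  ord <- order(calls$chrom, calls$start)
  expect_equal(back[, c("chrom", "start", "end")],
               calls[ord, c("chrom", "start", "end")],
               ignore_attr = TRUE)
  expect_equal(back$genotype, calls$genotype[ord])

  cons <- calls
  cons$matched_ro <- runif(5, 0.6, 1)
  cons$caller_primary <- "manta"; cons$caller_secondary <- "lumpy"
  p2 <- tempfile(fileext = ".vcf")
  write_consensus_vcf(cons, p2)
  back2 <- suppressMessages(read_deletions_vcf(p2, "consensus"))
  expect_equal(back2[, c("chrom", "start", "end")],
               cons[ord, c("chrom", "start", "end")], ignore_attr = TRUE)
  expect_equal(back2$genotype, cons$genotype[ord])
  expect_true(any(grepl("CALLERS=manta,lumpy", readLines(p2))))
})

test_that("a simulated annotation survives the GFF3 round trip", {
  cfg <- small_config(42)
  ann <- simulate_annotation(cfg)
  p <- tempfile(fileext = ".gff3")
  delscan:::write_gff3(ann, p)
  back <- read_gff3(p)
  expect_equal(back$genes, ann$genes)
  expect_equal(back$exons[, c("gene_id", "chrom", "start", "end")],
               ann$exons[, c("gene_id", "chrom", "start", "end")])
})

test_that("BED, GMT and hits TSV readers honour their contracts", {
  p <- tempfile()
  writeLines("chr1\t999\t1500", p)
  expect_equal(read_bed(p),
               data.frame(chrom = "chr1", start = 999L, end = 1500L),
               ignore_attr = TRUE)
  b <- intervals(c("chr2", "chr1"), c(10, 0), c(20, 5))
  write_bed(b, p)
  expect_equal(read_bed(p)[, 1:3], b[, 1:3], ignore_attr = TRUE)

  writeLines(c("pathA\tdesc\tg1\tg2", "short_line\tonly2fields"), p)
  expect_warning(sets <- read_gmt(p), "skipped")
  expect_equal(sets$pathA, c("g1", "g2"))
  expect_equal(length(sets), 1L)
  write_gmt(sets, p)
  expect_equal(suppressWarnings(read_gmt(p))$pathA, c("g1", "g2"))

  writeLines("m1\tchr1\t98.5\t70\t1\t0\t1\t70\t500\t431\tnot_a_number\t120", p)
  expect_error(read_hits_tsv(p), "evalue")
  writeLines("m1\tchr1\t98.5\t70\t1\t0\t1\t70\t500\t431\t1e-30\t120", p)
  hits <- read_hits_tsv(p)
  expect_equal(hits$evalue, 1e-30)
  expect_equal(hits$sstart, 500L)
})

test_that("interval constructor enforces its invariants", {
  expect_error(intervals("chr1", 10, 10), "start")
  expect_error(intervals("chr1", -1, 10), "start")
  expect_silent(intervals("chr1", 0, 1))
})
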