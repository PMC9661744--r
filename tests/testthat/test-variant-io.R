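test_that("toy VCF parses into typed variant calls", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"vaf\">",
    "##INFO=<ID=ALT_READS,Number=1,Type=Integer,Description=\"reads\">",
    "##INFO=<ID=POP_FREQ,Number=1,Type=Float,Description=\"popfreq\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"class\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"gene\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    paste("chr7", "55249071", ".", "C", "T", ".", "PASS",
          "VAF=0.23;ALT_READS=460;POP_FREQ=0;CLASS=SNV;GENE=EGFR",
          sep = "\t"),
    paste("chr17", "7578406", ".", "CA", "C", ".", "PASS",
          "VAF=0.05;ALT_READS=100;CLASS=SNV;GENE=TP53", sep = "\t"),
    paste("chr7", "55000000", ".", "N", "<DUP>", ".", "PASS",
          "CLASS=CNV_gain;GENE=EGFR", sep = "\t")), path)
  calls <- read_variant_file(path, "S1")
  expect_equal(nrow(calls), 3L)
  expect_equal(calls$variant_class, c("SNV", "SNV", "CNV_gain"))
  expect_equal(calls$pos, c(55249071L, 7578406L, 55000000L))
  expect_equal(calls$vaf, c(0.23, 0.05, NA))
  expect_true(is.na(calls$alt_reads[3]))
})

test_that("header-only VCF yields an empty call set", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"vaf\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")), path)
  expect_equal(nrow(read_variant_file(path, "S1")), 0L)
})

test_that("a VAF-bearing record without VAF is a parse error", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"class\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    paste("chr1", "100", ".", "A", "G", ".", "PASS", "CLASS=SNV",
          sep = "\t")), path)
  expect_error(read_variant_file(path, "S1"), "chr1:100")
  expect_error(read_variant_file("/nonexistent.vcf", "S1"), "not found")
})

test_that("each filter rule drops exactly the calls that violate it", {
  calls <- variant_calls(
    patient_id = "P1", sample_id = "S1",
    gene = c("EGFR", "TP53", "KRAS", "ALK", "MET"),
    chrom = "chr1", pos = 1:5, ref = "A", alt = "T",
    variant_class = "SNV",
    vaf = c(0.05, 0.001, 0.003, 0.02, 0.04),
    alt_reads = c(10L, 5L, 2L, 8L, 6L),
    pop_freq = c(0, 0, 0, 0.02, 0))
  kept <- apply_filters(calls)
  # hand enumeration: 0.001 fails VAF, 0.003 fails reads, 0.02 fails
  # population frequency; 0.05 and 0.04 survive
  expect_equal(kept$vaf, c(0.05, 0.04))
  expect_equal(kept$gene, c("EGFR", "MET"))
})

test_that("filters are inclusive at printed thresholds and CNVs bypass", {
  border <- variant_calls(
    patient_id = "P", sample_id = "S", gene = "TP53", chrom = "chr17",
    pos = 1L, ref = "C", alt = "T", variant_class = "SNV",
    vaf = 0.002, alt_reads = 3L, pop_freq = 0.01)
  expect_equal(nrow(apply_filters(border)), 1L)

  cnv <- variant_calls(
    patient_id = "P", sample_id = "S", gene = "EGFR", chrom = "chr7",
    pos = 2L, ref = "N", alt = "<DUP>", variant_class = "CNV_gain")
  expect_equal(nrow(apply_filters(cnv)), 1L)
  bl <- filter_config(blacklist = variant_key(cnv))
  expect_equal(nrow(apply_filters(cnv, bl)), 0L)
})

test_that("filtering is idempotent, order-preserving, and rule-complete", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(1:30, 1)
    calls <- variant_calls(
      patient_id = "P", sample_id = "S",
      gene = sample(c("EGFR", "TP53"), n, TRUE),
      chrom = "chr1", pos = sample.int(1e6, n), ref = "A", alt = "G",
      variant_class = sample(c("SNV", "indel", "fusion"), n, TRUE),
      vaf = round(runif(n, 0, 0.02), 4),
      alt_reads = sample(0:10, n, TRUE),
      pop_freq = ifelse(runif(n) < 0.5, round(runif(n, 0, 0.03), 4),
                        NA_real_))
    cfg <- filter_config()
    kept <- apply_filters(calls, cfg)
    expect_identical(apply_filters(kept, cfg), kept)
    expect_true(all(variant_key(kept) %in% variant_key(calls)))
    # every excluded call violates at least one named rule
    dropped <- calls[!variant_key(calls) %in% variant_key(kept), ,
                     drop = FALSE]
    if (nrow(dropped)) {
      viol <- dropped$vaf < cfg$min_vaf |
        dropped$alt_reads < cfg$min_alt_reads |
        (!is.na(dropped$pop_freq) & dropped$pop_freq > cfg$max_pop_freq)
      expect_true(all(viol))
    }
    # order preserved
    expect_false(is.unsorted(match(variant_key(kept), variant_key(calls))))
  }
})

test_that("ctDNA metrics follow the hGE formula", {
  p <- profile_with_vafs(0.10, cfdna = 33)
  expect_equal(ctdna_concentration(p), 1.0)
  expect_equal(ctdna_concentration(profile_with_vafs(numeric(0), 500)), 0)
  p3 <- profile_with_vafs(c(0.02, 0.04, 0.06), cfdna = 330)
  expect_equal(ctdna_concentration(p3), 4.0)
  expect_equal(max_vaf(p3), 0.06)
  expect_equal(max_vaf(profile_with_vafs(0.002)), 0.002)
  # CNV-only sample: positive, but no VAF-bearing variant
  cnv <- variant_calls(
    patient_id = "P1", sample_id = "S1", gene = "EGFR", chrom = "chr7",
    pos = 1L, ref = "N", alt = "<DUP>", variant_class = "CNV_gain")
  pc <- sample_profile("S1", "P1", "CSF", "baseline", 500, cnv)
  expect_equal(max_vaf(pc), 0)
  expect_equal(ctdna_concentration(pc), 0)
  expect_true(pc$is_positive)
})

test_that("concentration is linear in cfDNA and maxVAF bounds meanVAF", {
  set.seed(4)
  for (rep in 1:20) {
    vafs <- runif(sample(1:8, 1), 0.002, 0.5)
    p1 <- profile_with_vafs(vafs, cfdna = 100)
    p2 <- profile_with_vafs(vafs, cfdna = 700)
    expect_equal(ctdna_concentration(p2), 7 * ctdna_concentration(p1))
    expect_gte(max_vaf(p1), mean_vaf(p1))
    expect_gte(mean_vaf(p1), 0)
  }
  expect_error(sample_profile("S", "P", "CSF", "baseline", -1), "negative")
})

test_that("variant files round-trip without loss", {
  set.seed(21)
  calls <- variant_calls(
    patient_id = "P7", sample_id = "S7",
    gene = c("EGFR", "TP53", "KRAS", "EGFR"),
    chrom = c("chr7", "chr17", "chr12", "chr7"),
    pos = c(55249071L, 7578406L, 25398284L, 55000000L),
    ref = c("C", "CA", "G", "N"), alt = c("T", "C", "T", "<DUP>"),
    variant_class = c("SNV", "indel", "SNV", "CNV_gain"),
    vaf = c(0.2345, 0.00213, 0.0456, NA),
    alt_reads = c(469L, 4L, 91L, NA),
    pop_freq = c(0, NA, 0.004, NA),
    is_driver = c(TRUE, FALSE, TRUE, TRUE),
    is_oncogenic = c(TRUE, FALSE, TRUE, TRUE))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_variant_file(calls, path)
  back <- read_variant_file(path, "S7", "P7")
  expect_identical(variant_key(back), variant_key(calls))
  expect_equal(back$vaf, calls$vaf)
  expect_equal(back$variant_class, calls$variant_class)
  expect_equal(back$alt_reads, calls$alt_reads)
  expect_equal(back$pop_freq, calls$pop_freq)
  expect_equal(back$is_driver, calls$is_driver)
})

test_that("manifest reading validates its contract", {
  dir <- withr::local_tempdir()
  man <- data.frame(patient_id = "P1", sample_id = "S1",
                    compartment = "CSF", timepoint = "baseline",
                    cfdna_pg_per_ml = 500, vcf_path = "vcf/S1.vcf")
  path <- file.path(dir, "manifest.tsv")
  write.table(man, path, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_manifest(path)
  expect_equal(got$vcf_path, file.path(dir, "vcf/S1.vcf"))

  bad <- man; bad$compartment <- "serum"
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_manifest(path), "compartment")
})
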