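test_that("genome reading normalises case and rejects bad input", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr", "ACGT"), fa)
  g <- read_genome(fa)
  expect_equal(length(g), 1L)
  expect_equal(unname(Biostrings::width(g)), 4L)

  writeLines(c(">chr desc", "acgt"), fa)
  expect_equal(as.character(read_genome(fa)[[1]]), "ACGT")

  writeLines(c(">chr", "ACGT", ">chr", "GGCC"), fa)
  expect_error(read_genome(fa), "duplicate replicon")

  writeLines(c(">chr", "ACRT"), fa)  # IUPAC code outside A/C/G/T/N
  expect_error(read_genome(fa), "outside")
})

test_that("annotation I/O keeps strand-aware start codons and validates", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr", strrep("ACGT", 600)), fa)
  genome <- read_genome(fa)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr\t.\tCDS\t1001\t2002\t.\t+\t0\tID=gA;locus_tag=gA",
    "chr\t.\tCDS\t101\t400\t.\t-\t0\tID=gB;locus_tag=gB"), gff)
  ann <- read_annotation(gff, genome)
  expect_equal(ann$features$start_codon_pos[ann$features$locus_tag ==
                                              "gA"], 1001)
  expect_equal(ann$features$start_codon_pos[ann$features$locus_tag ==
                                              "gB"], 400)

  # CDS length not a multiple of 3: warn but keep
  writeLines(c(
    "##gff-version 3",
    "chr\t.\tCDS\t1\t100\t.\t+\t0\tID=gC;locus_tag=gC"), gff)
  expect_warning(ann2 <- read_annotation(gff, genome),
                 "multiple of 3")
  expect_equal(nrow(ann2$features), 1L)

  # out of bounds and missing locus_tag are errors
  writeLines(c(
    "##gff-version 3",
    "chr\t.\tCDS\t2300\t9000\t.\t+\t0\tID=gD;locus_tag=gD"), gff)
  expect_error(read_annotation(gff, genome), "bounds")
  writeLines(c(
    "##gff-version 3",
    "chr\t.\tCDS\t10\t309\t.\t+\t0\tID=gE"), gff)
  expect_error(read_annotation(gff, genome), "locus_tag")
})

test_that("wiggle coverage reading is dense, strict and round-trips", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr", strrep("A", 100)), fa)
  genome <- read_genome(fa)
  fwd <- withr::local_tempfile(fileext = ".wig")
  rev <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("variableStep chrom=chr", "10 5"), fwd)
  writeLines("variableStep chrom=chr", rev)
  tr <- read_coverage(fwd, rev, genome, "lib1")
  expect_equal(tr$counts$chr$fwd[10], 5L)
  expect_equal(sum(tr$counts$chr$fwd), 5L)
  expect_equal(sum(tr$counts$chr$rev), 0L)
  expect_equal(tr$library_size, 5)

  writeLines(c("variableStep chrom=chr", "10 5", "10 3"), fwd)
  expect_error(read_coverage(fwd, rev, genome, "lib1"), "duplicate")
  writeLines(c("variableStep chrom=chr", "200 5"), fwd)
  expect_error(read_coverage(fwd, rev, genome, "lib1"))

  set.seed(1)
  counts <- list(chr = list(fwd = rpois(100, 0.5),
                            rev = rpois(100, 0.5)))
  t0 <- coverage_track(counts, "x", "c", TRUE)
  write_coverage(t0, fwd, rev)
  t1 <- read_coverage(fwd, rev, genome, "x", "c", TRUE)
  expect_identical(lapply(t1$counts$chr, as.integer),
                   lapply(t0$counts$chr, as.integer))
})

test_that("TSS tables round-trip with one row per assignment", {
  rec <- data.frame(seqid = "chr", pos = c(100L, 100L, 250L),
                    strand = c("+", "+", "-"),
                    class = c("iTSS", "pTSS", "oTSS"),
                    locus_tag = c("gA", "gB", NA),
                    distance = c(NA, 40, NA),
                    height = c(12.5, 12.5, 8),
                    enrichment_factor = c(4, 4, 10),
                    detected_in = "c1",
                    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tss_table(rec, path)
  back <- read_tss_table(path)
  expect_equal(nrow(back), 3L)  # multi-class TSS keeps one row per class
  expect_equal(back$class, rec$class)
  expect_equal(back$height, rec$height)

  write_tss_table(rec[0, ], path)
  expect_equal(nrow(read_tss_table(path)), 0L)
})

test_that("config files round-trip and reject unknown keys", {
  cfg <- default_config()
  cfg$detection$min_height <- 12
  path <- withr::local_tempfile(fileext = ".cfg")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$detection$min_height, 12)
  expect_equal(back$classification$max_upstream,
               cfg$classification$max_upstream)
  writeLines("detection.bogus_key=1", path)
  expect_error(read_config(path), "unknown config key")
})
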