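test_that("5'-UTR length and class flags follow the definitions", {
  expect_equal(utr_length(981L, "+", 1001L), 20L)
  expect_equal(utr_length(1001L, "+", 1001L), 0L)
  expect_equal(utr_length(993L, "+", 1001L), 8L)   # leaderless boundary
  expect_equal(utr_length(1020L, "-", 1001L), 19L)
  expect_error(utr_length(1010L, "+", 1001L), "internal")

  lens <- c(0L, 8L, 9L, 16L, 49L, 50L, 300L)
  utrs <- data.frame(utr_length = lens,
                     leaderless = lens <= 8, long_utr = lens >= 50,
                     utr_gc = 50, rbs_found = FALSE)
  expect_true(all(utrs$leaderless == (utrs$utr_length <= 8)))
  expect_false(any(utrs$leaderless & utrs$long_utr))
})

test_that("UTR summaries report median and class fractions", {
  mk <- function(lens) data.frame(
    utr_length = lens, leaderless = lens <= 8,
    long_utr = lens >= 50 & lens <= 300, utr_gc = 50,
    rbs_found = FALSE)
  s <- classify_utrs(mk(c(0L, 16L, 40L)))
  expect_equal(s$median_utr, 16)
  s2 <- classify_utrs(mk(c(0L, 3L, 8L)))
  expect_equal(s2$leaderless_fraction, 1)
  expect_error(classify_utrs(mk(16L)[0, ]), "empty")
})

test_that("UTR annotation finds planted RBS hexamers", {
  # gene at 1001 with UTR 20; RBS GGAGGA ending 6 nt before the start
  g <- random_seq(2000, 0.42)
  substr(g, 989, 994) <- "GGAGGA"
  ann <- tiny_annotation(data.frame(
    locus_tag = "gA", start = 1001L, end = 1300L, strand = "+",
    stringsAsFactors = FALSE), genome_seq = g)
  rec <- assign_primary_secondary(classify_tss(
    data.frame(seqid = "chr", pos = 981L, strand = "+", height = 10),
    ann))
  u <- annotate_utrs(rec, ann)
  expect_equal(u$utr_length, 20L)
  expect_true(u$rbs_found)
  expect_equal(u$rbs_seq, "GGAGGA")
  expect_equal(u$rbs_spacer, 6L)
})

test_that("start re-assignment applies the GTG-to-ATG review rule", {
  # annotated GTG start with UTR 3 nt, in-frame ATG 3 codons downstream,
  # RBS planted upstream of the ATG
  utr <- "TAG"  # 3 nt UTR (not in frame with anything upstream)
  cds <- paste0("GTG", "GGA", "GGC", "ATG",
                strrep("GAA", 30), "TAA")
  g <- paste0(random_seq(997, 0.42), utr, cds, random_seq(500, 0.42))
  ann <- tiny_annotation(data.frame(
    locus_tag = "gA", start = 1001L, end = 1000L + nchar(cds),
    strand = "+", stringsAsFactors = FALSE), genome_seq = g)
  r <- reassign_start_codon(ann, "gA", 998L)
  expect_false(is.null(r))
  expect_equal(r$new_start, 1010L)
  expect_equal(r$new_codon, "ATG")
  expect_equal(r$frame_offset_codons, 3L)
  expect_equal(r$old_utr, 3L)
  expect_equal(r$new_utr, 12L)   # no longer leaderless
  expect_true(r$rbs_found)       # GGAGGC matches GGDGRD

  # no alternative start in the window: no re-assignment
  cds2 <- paste0("GTG", strrep("GAA", 40), "TAA")
  g2 <- paste0(random_seq(997, 0.42), "TAG", cds2,
               random_seq(500, 0.42))
  ann2 <- tiny_annotation(data.frame(
    locus_tag = "gA", start = 1001L, end = 1000L + nchar(cds2),
    strand = "+", stringsAsFactors = FALSE), genome_seq = g2)
  expect_null(reassign_start_codon(ann2, "gA", 998L))
})

test_that("re-assignment never shortens the UTR or breaks the frame", {
  sim <- simulate_genome(sim_params(n_genes = 120, seed = 23))
  tracks <- simulate_tracks(sim)
  tss <- detect_tss(tracks$treated, tracks$untreated)
  rec <- assign_primary_secondary(classify_tss(tss, sim$annotation))
  re <- reassign_start_codons(rec, sim$annotation)
  expect_gt(nrow(re), 0L)
  expect_true(all(re$new_utr > re$old_utr))
  expect_true(all((re$new_utr - re$old_utr) %% 3 == 0))
  expect_true(all(re$new_codon %in% c("ATG", "GTG", "TTG")))
  # recovered exactly the planted mis-annotations
  mis <- sim$truth$misannotations
  expect_equal(sort(re$locus_tag), sort(mis$locus_tag))
  m <- merge(re, mis, by = "locus_tag")
  expect_equal(m$new_start, m$true_start)
  expect_equal(m$frame_offset_codons, m$offset_codons)

  # applying the changes clears the affected leaderless records and is
  # idempotent
  rc <- recategorize(tss, re, sim$annotation)
  aff <- rc$utrs[rc$utrs$locus_tag %in% re$locus_tag, ]
  expect_false(any(aff$leaderless))
  expect_equal(nrow(reassign_start_codons(rc$records, rc$annotation)),
               0L)

  # empty re-assignment set leaves records unchanged
  rc0 <- recategorize(tss, re[0, ], sim$annotation)
  expect_equal(rc0$records, rec)
})

test_that("internal TSS near the start can be re-categorised as primary", {
  # iTSS 30 bp into the gene; further downstream an in-frame ATG with an
  # RBS six nt upstream of it
  cds <- paste0("GTG", strrep("CCA", 13),               # 39 nt
                "GGAGGA", "CACCAA", "ATG", strrep("GAA", 30), "TAA")
  g <- paste0(random_seq(1000, 0.42), cds, random_seq(500, 0.42))
  ann <- tiny_annotation(data.frame(
    locus_tag = "gA", start = 1001L, end = 1000L + nchar(cds),
    strand = "+", stringsAsFactors = FALSE), genome_seq = g)
  tss <- data.frame(seqid = "chr", pos = 1031L, strand = "+",
                    height = 10)
  rec <- assign_primary_secondary(classify_tss(tss, ann))
  expect_equal(rec$class, "iTSS")
  re <- reassign_start_codons(rec, ann)
  expect_equal(nrow(re), 1L)
  expect_equal(re$new_codon, "ATG")
  rc <- recategorize(tss, re, ann)
  expect_true("pTSS" %in% rc$records$class)
})
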