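make_two_gene_ann <- function() {
  tiny_annotation(data.frame(
    locus_tag = c("gA", "gB"), start = c(1001L, 2500L),
    end = c(2000L, 3000L), strand = c("+", "+"),
    stringsAsFactors = FALSE))
}

tss_row <- function(pos, strand, height = 10) data.frame(
  seqid = "chr", pos = pos, strand = strand, height = height,
  stringsAsFactors = FALSE)

test_that("positional class definitions follow the window geometry", {
  ann <- make_two_gene_ann()
  # 50 bp upstream on the sense strand
  r <- classify_tss(tss_row(951L, "+"), ann)
  expect_equal(r$class, "upstream")
  expect_equal(r$locus_tag, "gA")
  expect_equal(r$distance, 50)
  # inside on the antisense strand
  r <- classify_tss(tss_row(1500L, "-"), ann)
  expect_true(all(r$class == "aTSS"))
  # antisense flank boundary: 100 bp past the gene end is in, 101 is not
  r <- classify_tss(tss_row(2100L, "-"), ann)
  expect_true("aTSS" %in% r$class)
  r <- classify_tss(tss_row(2101L, "-"), ann)
  expect_false("aTSS" %in% r$class[r$locus_tag %in% "gA"])
  # 351 bp upstream with nothing else around: orphan
  r <- classify_tss(tss_row(650L, "+"), ann)
  expect_equal(r$class, "oTSS")
  expect_true(is.na(r$locus_tag))
  # upstream boundary is inclusive at 300
  r <- classify_tss(tss_row(701L, "+"), ann)
  expect_equal(r$class, "upstream")
  # TSS at the start codon's first base: upstream with UTR 0, not internal
  r <- classify_tss(tss_row(1001L, "+"), ann)
  expect_equal(r$class, "upstream")
  expect_equal(r$distance, 0)
})

test_that("a TSS can be internal and upstream at once", {
  ann <- tiny_annotation(data.frame(
    locus_tag = c("gA", "gB"), start = c(1001L, 2100L),
    end = c(2000L, 2600L), strand = "+", stringsAsFactors = FALSE))
  r <- classify_tss(tss_row(1900L, "+"), ann)
  expect_setequal(paste(r$class, r$locus_tag),
                  c("iTSS gA", "upstream gB"))
})

test_that("primary/secondary assignment ranks by reads, ties upstream", {
  ann <- make_two_gene_ann()
  tss <- rbind(tss_row(760L, "+", 30), tss_row(900L, "+", 100),
               tss_row(950L, "+", 60))
  rec <- assign_primary_secondary(classify_tss(tss, ann))
  expect_equal(rec$class[rec$pos == 900L], "pTSS")
  expect_setequal(rec$class[rec$pos != 900L], "sTSS")
  expect_equal(sum(rec$class == "pTSS"), 1L)

  tie <- rbind(tss_row(900L, "+", 100), tss_row(950L, "+", 100))
  rec2 <- assign_primary_secondary(classify_tss(tie, ann))
  expect_equal(rec2$class[rec2$pos == 900L], "pTSS")  # more upstream

  single <- assign_primary_secondary(classify_tss(tss_row(990L, "+"),
                                                  ann))
  expect_equal(single$class, "pTSS")
})

test_that("category summary counts assignments and overlaps", {
  ann <- tiny_annotation(data.frame(
    locus_tag = c("gA", "gB"), start = c(1001L, 2100L),
    end = c(2000L, 2600L), strand = "+", stringsAsFactors = FALSE))
  tss <- rbind(tss_row(1900L, "+", 50),   # iTSS(gA) + pTSS(gB)
               tss_row(700L, "+", 10))    # oTSS
  rec <- assign_primary_secondary(classify_tss(tss, ann))
  s <- category_summary(rec)
  expect_equal(s$n_tss, 2L)
  expect_equal(s$n_assignments, 3L)
  expect_gte(s$n_assignments, s$n_tss)
  expect_equal(unname(s$class_counts["oTSS"]), 1L)
  expect_equal(s$overlap["iTSS", "pTSS"], 1L)
  # oTSS exclusivity
  otss_keys <- with(rec, paste(pos, strand)[class == "oTSS"])
  expect_false(any(otss_keys %in%
                   with(rec, paste(pos, strand)[class != "oTSS"])))
})

test_that("antisense terminus buckets follow the 150 bp windows", {
  ann <- tiny_annotation(data.frame(
    locus_tag = "gA", start = 2001L, end = 3000L, strand = "+",
    stringsAsFactors = FALSE))
  # exactly at the stop codon, opposite strand: 3' bucket
  at_stop <- assign_primary_secondary(classify_tss(tss_row(3000L, "-"),
                                                   ann))
  te <- terminus_enrichment(at_stop, ann, 150)
  expect_equal(te$n_3prime, 1L)
  expect_equal(te$n_5prime, 0L)
  expect_equal(te$frac_terminus, 1)
  # gene midpoint of a 1 kb gene: neither bucket
  mid <- assign_primary_secondary(classify_tss(tss_row(2500L, "-"),
                                               ann))
  te2 <- terminus_enrichment(mid, ann, 150)
  expect_equal(te2$n_neither, 1L)
  expect_equal(te2$frac_terminus, 0)
})

test_that("classifier agrees with a naive gene-by-gene oracle", {
  set.seed(11)
  for (layout in 1:120) {
    n_genes <- sample(2:6, 1L)
    starts <- sort(sample.int(4000L, n_genes)) + c(0L, rep(200L,
                                                           n_genes - 1L))
    genes <- data.frame(
      locus_tag = paste0("g", seq_len(n_genes)),
      start = starts,
      end = starts + sample(150:900, n_genes, replace = TRUE),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      stringsAsFactors = FALSE)
    genes <- genes[genes$end <= 9000L, , drop = FALSE]
    if (!nrow(genes)) next
    ann <- tiny_annotation(genes, length = 9000L)
    for (k in 1:12) {
      pos <- sample.int(9000L, 1L)
      strand <- sample(c("+", "-"), 1L)
      expect_identical(
        pkg_classify_set(tss_row(pos, strand), ann),
        brute_classify(pos, strand, ann$features),
        info = sprintf("layout %d pos %d%s", layout, pos, strand))
    }
  }
})

test_that("classes recover the planted ground truth on synthetic data", {
  sim <- simulate_genome(sim_params(n_genes = 80, seed = 19))
  tracks <- simulate_tracks(sim)
  tss <- detect_tss(tracks$treated, tracks$untreated)
  rec <- assign_primary_secondary(classify_tss(tss, sim$annotation))
  truth <- sim$truth$tss
  cnt <- category_summary(rec)$class_counts
  planted <- table(factor(truth$class,
                          levels = c("pTSS", "sTSS", "iTSS", "aTSS",
                                     "oTSS")))
  # every planted class count is recovered at least in full (multi-class
  # geometry can only add assignments)
  expect_true(all(cnt >= as.integer(planted) - 1L))
  # planted labels with single-class geometry match exactly
  for (i in seq_len(nrow(truth))) {
    oracle <- brute_classify(truth$pos[i], truth$strand[i],
                             sim$annotation$features)
    if (length(oracle) != 1L) next
    j <- which(tss$strand == truth$strand[i] &
               abs(tss$pos - truth$pos[i]) <= 1)
    expect_length(j, 1L)
    got <- rec[rec$pos == tss$pos[j] & rec$strand == tss$strand[j], ]
    if (truth$class[i] %in% c("pTSS", "sTSS"))
      expect_true(all(got$class %in% c("pTSS", "sTSS")))
    else expect_equal(unique(got$class), truth$class[i])
  }
})
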