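test_that("generation is deterministic and byte-stable on disk", {
  p <- sim_params(n_genes = 25, seed = 4)
  s1 <- simulate_genome(p)
  s2 <- simulate_genome(p)
  expect_identical(as.character(s1$annotation$genome),
                   as.character(s2$annotation$genome))
  expect_identical(s1$truth, s2$truth)
  files <- replicate(2, {
    fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
    Biostrings::writeXStringSet(s1$annotation$genome, fa)
    suppressWarnings(write_annotation(s1$annotation, gff))
    c(fa, gff)
  })
  expect_identical(readLines(files[1, 1]), readLines(files[1, 2]))
  expect_identical(readLines(files[2, 1]), readLines(files[2, 2]))
  t1 <- simulate_coverage(s1, "S_exp", TRUE, 99)
  t2 <- simulate_coverage(s2, "S_exp", TRUE, 99)
  expect_identical(t1$counts, t2$counts)
  expect_error(simulate_coverage(s1, "bogus", TRUE, 1),
               "unknown condition")
})

test_that("UTR mixture extremes plant what they say", {
  s0 <- simulate_genome(sim_params(n_genes = 30, seed = 2,
                                   leaderless_fraction = 0,
                                   misannotation_count = 0))
  expect_false(any(s0$truth$utr_lengths <= 8))
  s1 <- simulate_genome(sim_params(n_genes = 30, seed = 2,
                                   leaderless_fraction = 1,
                                   long_utr_fraction = 0,
                                   misannotation_count = 0))
  expect_true(all(s1$truth$utr_lengths <= 8))
})

test_that("planted UTR statistics hit the configured mixture", {
  sim <- simulate_genome(sim_params(n_genes = 1000, seed = 6))
  u <- sim$truth$utr_lengths
  expect_gte(length(u), 500L)
  expect_lte(abs(median(u) - 16), 1)
  expect_lte(abs(mean(u <= 8) - 0.14), 0.03)
  expect_lte(abs(mean(u >= 50 & u <= 300) - 0.20), 0.03)
})

test_that("the TEX contract holds at primary and processing sites", {
  # all diffuse read sources off: only planted peaks remain
  p <- sim_params(n_genes = 30, seed = 8, noise = 0, smear_prob = 0,
                  body_read_rate = 0)
  sim <- simulate_genome(p)
  tr <- simulate_coverage(sim, "S_exp", TRUE, 1)
  un <- simulate_coverage(sim, "S_exp", FALSE, 2)
  truth <- sim$truth$tss
  active <- truth$exp_S_exp > 0
  get_at <- function(track, pos, strand) {
    v <- if (strand == "+") track$counts[[1]]$fwd else
      track$counts[[1]]$rev
    v[pos]
  }
  t_sum <- sum(mapply(get_at, list(tr), truth$pos[active],
                      truth$strand[active]))
  u_sum <- sum(mapply(get_at, list(un), truth$pos[active],
                      truth$strand[active]))
  # expected treated:untreated ratio at primary sites is 1/0.30
  expect_gt(t_sum / u_sum, 2)
  # Poisson sum oracle: totals within 3 sigma of the planted expectation
  lambda <- sum(truth$exp_S_exp)
  expect_lt(abs(t_sum - lambda), 3 * sqrt(lambda) + 1)
  # processing sites appear only without TEX
  pr <- sim$truth$processing
  lvl <- sim$truth$expression[pr$tu, "S_exp"]
  pr_t <- sum(mapply(get_at, list(tr), pr$pos, pr$strand))
  pr_u <- sum(mapply(get_at, list(un), pr$pos[lvl > 0],
                     pr$strand[lvl > 0]))
  expect_equal(pr_t, 0)
  expect_gt(pr_u, 0)
  # two seeds differ but agree in expectation
  un2 <- simulate_coverage(sim, "S_exp", FALSE, 3)
  expect_false(identical(un$counts, un2$counts))
})

test_that("planted class labels satisfy the geometric definitions", {
  sim <- simulate_genome(sim_params(n_genes = 60, seed = 13))
  truth <- sim$truth$tss
  for (i in seq_len(nrow(truth))) {
    oracle <- brute_classify(truth$pos[i], truth$strand[i],
                             sim$annotation$features)
    kinds <- sub(":.*", "", oracle)
    want <- switch(truth$class[i],
                   pTSS = "upstream", sTSS = "upstream",
                   iTSS = "iTSS", aTSS = "aTSS", oTSS = "oTSS")
    expect_true(want %in% kinds,
                info = paste(truth$class[i], truth$pos[i]))
    if (truth$class[i] %in% c("pTSS", "sTSS"))
      expect_true(paste0("upstream:", truth$locus_tag[i]) %in% oracle)
  }
  # every pTSS lies within 300 bp of its gene's start codon; leaderless
  # genes start at most 8 nt downstream
  ft <- sim$annotation$features
  p <- truth[truth$class == "pTSS", ]
  scp <- ft$start_codon_pos[match(p$locus_tag, ft$locus_tag)]
  d <- ifelse(p$strand == "+", scp - p$pos, p$pos - scp)
  expect_true(all(d >= 0 & d <= 300))
})

test_that("ground truth tables round-trip through TSV", {
  sim <- simulate_genome(sim_params(n_genes = 25, seed = 9))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(sim, path)
  back <- read_truth(path)
  expect_equal(nrow(back), nrow(sim$truth$tss))
  expect_true(all(back$class %in%
                  c("pTSS", "sTSS", "iTSS", "aTSS", "oTSS")))
  expect_equal(back$pos, sim$truth$tss$pos)
  expect_equal(back$exp_S_exp, sim$truth$tss$exp_S_exp)
})

test_that("antisense termini are planted at the configured fraction", {
  sim <- simulate_genome(sim_params(n_genes = 400, seed = 14))
  a <- sim$truth$tss[sim$truth$tss$class == "aTSS", ]
  expect_gte(nrow(a), 150L)
  expect_lte(abs(mean(a$terminus != "none") - 0.58), 0.05)
})
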