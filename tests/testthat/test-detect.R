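test_that("track normalisation follows the per-million contract", {
  cnt <- integer(100); cnt[7] <- 50L
  tr <- coverage_track(list(chr = list(fwd = cnt, rev = integer(100))),
                       "a", "c", TRUE)
  tr$library_size <- 1e6  # pretend depth
  expect_equal(normalize_track(tr)$chr$fwd[7], 50)
  expect_equal(normalize_track(tr, per_million = FALSE)$chr$fwd[7], 50)

  tr2 <- tiny_track(100, fwd = c(`10` = 30, `20` = 10))
  expect_equal(sum(unlist(normalize_track(tr2)$chr)), 1e6)
  tr0 <- tiny_track(10)
  expect_error(normalize_track(tr0), "zero library size")
})

test_that("step and enrichment statistics match hand arithmetic", {
  # equal library sizes so normalised ratios equal raw ratios
  tre <- tiny_track(100, fwd = c(`50` = 40, `90` = 10))
  unt <- tiny_track(100, fwd = c(`50` = 8, `70` = 42), treated = FALSE)
  f <- 1e6 / 50  # both libraries hold 50 reads
  m <- step_metrics(tre, unt, "chr", 50, "+",
                    detection_params(pseudocount = f))
  expect_equal(unname(m["enrichment_factor"]), 40 / 9)
  expect_equal(unname(m["step_factor"]), 40 / 1)  # upstream empty
  expect_equal(unname(m["raw"]), 40)

  # untreated zero at the position: enrichment = height / pseudocount
  m2 <- step_metrics(tre, unt, "chr", 90, "+",
                     detection_params(pseudocount = f))
  expect_equal(unname(m2["enrichment_factor"]), 10)
})

test_that("candidate calling applies all three thresholds", {
  # ballast on the far end gives both libraries a common 1000-read scale
  # so per-million heights are comparable
  ballast <- function(fwd, total = 1000, treated = TRUE)
    tiny_track(200, fwd = fwd,
               rev = c(`190` = total - sum(fwd)), treated = treated)
  tre <- ballast(c(`100` = 40))
  unt <- ballast(c(`100` = 2), treated = FALSE)
  out <- call_candidates(tre, unt)
  expect_equal(out$pos, 100L)
  expect_equal(out$strand, "+")
  expect_equal(out$raw, 40)

  # flat coverage: no step, no calls on the flat strand
  flat <- coverage_track(list(chr = list(fwd = rep(10L, 200),
                                         rev = integer(200))),
                         "f", "c", TRUE)
  out2 <- call_candidates(flat, unt)
  # no interior position has a step (the replicon edge itself has an
  # undefined upstream neighbour and is scored against the pseudocount)
  expect_false(any(out2$strand == "+" & out2$pos > 1L))

  # equal treated and untreated heights: no TEX enrichment, no call
  tre3 <- ballast(c(`100` = 40))
  unt3 <- ballast(c(`100` = 40), treated = FALSE)
  expect_false(100L %in% call_candidates(tre3, unt3)$pos)

  # minus strand: upstream neighbour is pos + 1
  trem <- tiny_track(200, rev = c(`100` = 40, `101` = 40, `10` = 920))
  untm <- tiny_track(200, rev = c(`100` = 2, `101` = 2, `10` = 996),
                     treated = FALSE)
  outm <- call_candidates(trem, untm)
  expect_true(101L %in% outm$pos)  # 101 has empty upstream at 102
  expect_false(100L %in% outm$pos) # 100 sits below the 101 step
})

test_that("raising any threshold never increases the number of calls", {
  set.seed(42)
  n <- 3000L
  tre <- coverage_track(list(chr = list(fwd = rpois(n, 0.3) +
                                          rpois(n, 0.1) * 20L,
                                        rev = rpois(n, 0.3))),
                        "t", "c", TRUE)
  unt <- coverage_track(list(chr = list(fwd = rpois(n, 0.5),
                                        rev = rpois(n, 0.5))),
                        "u", "c", FALSE)
  base <- nrow(call_candidates(tre, unt, detection_params()))
  for (p in list(detection_params(min_height = 8),
                 detection_params(min_step_factor = 4),
                 detection_params(min_enrichment = 4))) {
    expect_lte(nrow(call_candidates(tre, unt, p)), base)
  }
})

test_that("clustering keeps the highest peak and matches single linkage", {
  cand <- data.frame(seqid = "chr", pos = c(100L, 101L, 103L),
                     strand = "+", height = c(10, 50, 7),
                     raw = c(10, 50, 7), step_factor = 5,
                     enrichment_factor = 5, library_id = "c1",
                     stringsAsFactors = FALSE)
  out <- cluster_candidates(cand, 3)
  expect_equal(out$pos, 101L)
  expect_equal(out$height, 50)

  # ties go to the most upstream position in transcription direction
  tie <- cand[1:2, ]; tie$height <- c(50, 50)
  expect_equal(cluster_candidates(tie, 3)$pos, 100L)
  tie$strand <- "-"
  expect_equal(cluster_candidates(tie, 3)$pos, 101L)

  # partition equivalence against a brute-force single-linkage oracle
  set.seed(7)
  for (rep in 1:60) {
    pos <- sort(sample.int(300L, 40L))
    win <- sample(1:4, 1L)
    df <- data.frame(seqid = "chr", pos = pos, strand = "+",
                     height = runif(40), raw = 5, step_factor = 5,
                     enrichment_factor = 5, library_id = "c1",
                     stringsAsFactors = FALSE)
    out <- cluster_candidates(df, win)
    oracle_groups <- brute_single_linkage(pos, win)
    expect_equal(nrow(out), length(unique(oracle_groups)))
    # every reported representative is its cluster's height maximum
    for (g in unique(oracle_groups)) {
      members <- df[oracle_groups == g, ]
      rep_row <- out[out$pos %in% members$pos, ]
      expect_equal(nrow(rep_row), 1L)
      expect_equal(rep_row$height, max(members$height))
    }
  }
})

test_that("library merging takes the union with position tolerance", {
  mk <- function(pos, h, lib) data.frame(
    seqid = "chr", pos = pos, strand = "+", height = h, raw = h,
    step_factor = 5, enrichment_factor = 5, library_id = lib,
    stringsAsFactors = FALSE)
  same <- lapply(c("a", "b", "c", "d"), function(l) mk(500L, 10, l))
  m <- merge_libraries(same)
  expect_equal(nrow(m), 1L)
  expect_equal(m$n_libraries, 4L)
  expect_equal(m$detected_in, "a,b,c,d")
  expect_equal(m$height, 40)

  near <- list(mk(500L, 10, "S_exp"), mk(501L, 30, "P_exp"))
  m2 <- merge_libraries(near, tolerance = 1)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$pos, 501L)  # highest summed height wins
  expect_equal(m2$height_S_exp, 10)
  expect_equal(m2$height_P_exp, 30)

  disjoint <- list(mk(100L, 10, "a"), mk(900L, 10, "b"))
  expect_equal(nrow(merge_libraries(disjoint)), 2L)
})

test_that("every reported TSS passes all three thresholds in a treated library", {
  sim <- simulate_genome(sim_params(n_genes = 40, seed = 3))
  tracks <- simulate_tracks(sim)
  params <- detection_params()
  tss <- detect_tss(tracks$treated, tracks$untreated, params)
  expect_gt(nrow(tss), 0L)
  per_cond <- lapply(names(tracks$treated), function(cond)
    call_candidates(tracks$treated[[cond]], tracks$untreated[[cond]],
                    params))
  all_cand <- do.call(rbind, per_cond)
  # the merged representative lies within the cluster window of a raw
  # candidate that satisfied height, step and enrichment
  for (i in seq_len(nrow(tss)))
    expect_true(match_within(tss$pos[i], tss$strand[i], all_cand,
                             tol = params$cluster_window))
})
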