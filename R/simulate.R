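#' Synthetic-data generator parameters
#'
#' Defaults encode the statistical structure the pipeline assumes in an
#' archaeal-style primary transcriptome: 42% GC coding sequence, a 5'-UTR
#' mixture with median 16 nt, 14% leaderless (at most 8 nt) and 20% long
#' UTRs (50-300 nt, median 103 nt, 48% GC), an RBS (GGDGRD) in half the
#' mRNAs, TATA box and BRE planted at median distances 23 and 33 bp
#' upstream of the TSS, 58% of antisense TSS within 150 bp of a gene
#' terminus, start-codon mis-annotations with an in-frame ATG 2-3 codons
#' downstream of an annotated GTG, four growth conditions with
#' condition-dependent silencing, and a reciprocal sulfur-switch operon
#' pair with a 16-fold expression swing.
#'
#' @param n_genes Number of genes (grouped into transcription units).
#' @param operon_size_probs Probabilities of TU sizes 1..k.
#' @param gc_coding,gc_intergenic,gc_long_utr GC fractions of coding,
#'   intergenic/short-UTR, and long-UTR sequence.
#' @param utr_median Target median 5'-UTR length (nt).
#' @param leaderless_fraction Fraction of mRNAs with UTR of at most 8 nt.
#' @param long_utr_fraction Fraction with UTR 50-300 nt.
#' @param long_utr_median Median of the long-UTR component (nt).
#' @param rbs_fraction Fraction of mRNAs with a planted RBS.
#' @param tata_offset_median,bre_offset_median Median distance from motif
#'   3' end to the TSS (bp).
#' @param offset_sd Gaussian jitter of the promoter offsets (bp).
#' @param tata_fraction,bre_fraction Fraction of primary TSS with a
#'   planted TATA box / BRE.
#' @param tata_consensus,bre_consensus Planted consensus sequences.
#' @param motif_match_prob Per-position probability that a planted motif
#'   base equals the consensus.
#' @param stss_prob Probability a TU gets a secondary TSS.
#' @param stss_rel_height Height of a secondary TSS relative to the
#'   primary.
#' @param itss_per_gene,atss_per_gene Planted internal/antisense TSS per
#'   gene.
#' @param n_otss Orphan TSS (each in its own gene desert).
#' @param atss_terminus_fraction Fraction of antisense TSS planted within
#'   `terminus_window` of a gene terminus.
#' @param terminus_window Terminus window (bp).
#' @param misannotation_count Genes annotated with a GTG start whose true
#'   ATG start is 2-3 codons downstream (RBS planted).
#' @param conditions Condition names.
#' @param silent_fractions Named fraction of TUs silent per condition
#'   (every TU is kept active in at least one condition).
#' @param depth Expected treated 5'-end reads at a primary TSS per unit
#'   expression level.
#' @param aux_depth_factor Depth multiplier for internal, antisense and
#'   orphan TSS.
#' @param processed_depth Expected untreated reads at a processing site
#'   for a host at expression level 2.
#' @param processing_sites_per_kb Planted processing sites per kb.
#' @param untreated_primary_fraction Relative depth of primary peaks in
#'   untreated libraries (TEX enriches, it does not create).
#' @param body_read_rate Untreated gene-body 5' ends per nt per unit
#'   level (transcript fragmentation and processing products).
#' @param treated_body_fraction TEX carry-over of body reads into treated
#'   libraries.
#' @param smear_prob Probability a peak read lands 1 nt off.
#' @param noise Background reads per nt per strand.
#' @param level_meanlog,level_sdlog,level_min,level_max Log-normal
#'   expression-level distribution (clipped).
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @return Named parameter list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 200,
                       operon_size_probs = c(0.61, 0.15, 0.10, 0.08,
                                             0.06),
                       gc_coding = 0.42, gc_intergenic = 0.40,
                       gc_long_utr = 0.48,
                       utr_median = 16, leaderless_fraction = 0.14,
                       long_utr_fraction = 0.20, long_utr_median = 103,
                       rbs_fraction = 0.50,
                       tata_offset_median = 23, bre_offset_median = 33,
                       offset_sd = 2,
                       tata_fraction = 0.90, bre_fraction = 0.90,
                       tata_consensus = "TTTATATA",
                       bre_consensus = "CGAAACG",
                       motif_match_prob = 0.93,
                       stss_prob = 0.25, stss_rel_height = 0.4,
                       itss_per_gene = 0.30, atss_per_gene = 0.50,
                       n_otss = 8,
                       atss_terminus_fraction = 0.58,
                       terminus_window = 150,
                       misannotation_count = 10,
                       conditions = c("S_exp", "S_stat", "P_exp", "PS"),
                       silent_fractions = c(S_exp = 0.28, S_stat = 0.87,
                                            P_exp = 0.35, PS = 0.35),
                       depth = 40, aux_depth_factor = 0.75,
                       processed_depth = 30,
                       processing_sites_per_kb = 1.0,
                       untreated_primary_fraction = 0.30,
                       body_read_rate = 0.5,
                       treated_body_fraction = 0.05,
                       smear_prob = 0.10, noise = 0.02,
                       level_meanlog = log(2), level_sdlog = 0.7,
                       level_min = 1, level_max = 16,
                       seed = 1) {
  p <- as.list(environment())
  fr <- c(p$leaderless_fraction, p$long_utr_fraction, p$rbs_fraction,
          p$tata_fraction, p$bre_fraction, p$atss_terminus_fraction,
          p$untreated_primary_fraction, p$smear_prob,
          p$motif_match_prob, p$silent_fractions)
  stopifnot(all(fr >= 0 & fr <= 1), p$depth > 0, p$n_genes >= 1,
            all(p$conditions %in% names(p$silent_fractions)))
  # the 50 bp promoter pad must hold the BRE at its largest jittered
  # offset; denser promoters cannot be planted
  if (p$bre_offset_median + 3 * p$offset_sd +
      nchar(p$bre_consensus) > PROMOTER_PAD)
    stop("promoter offsets too large for the ", PROMOTER_PAD,
         " bp promoter window; reduce bre_offset_median or offset_sd")
  class(p) <- "sim_params"
  p
}

PROMOTER_PAD <- 50L

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (is.null(old))
            suppressWarnings(rm(list = ".Random.seed",
                                envir = globalenv()))
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# sample() collapses a length-1 vector to 1:x; this never does
sample1 <- function(x) x[sample.int(length(x), 1L)]

shuffle <- function(x) x[sample.int(length(x))]

random_dna <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# codons at the requested GC, never a stop; optionally never a start
random_codons <- function(n, gc, exclude_starts = logical(n)) {
  if (n == 0L) return(character(0))
  stops <- c("TAA", "TAG", "TGA")
  starts <- c("ATG", "GTG", "TTG")
  out <- character(n)
  todo <- seq_len(n)
  while (length(todo)) {
    cand <- vapply(todo, function(i) random_dna(3L, gc), character(1))
    bad <- cand %in% stops | (exclude_starts[todo] & cand %in% starts)
    out[todo[!bad]] <- cand[!bad]
    todo <- todo[bad]
  }
  out
}

mutate_consensus <- function(consensus, match_prob) {
  b <- strsplit(consensus, "")[[1L]]
  flip <- runif(length(b)) > match_prob
  b[flip] <- vapply(b[flip], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1))
  paste(b, collapse = "")
}

draw_levels <- function(n, p) {
  pmin(pmax(stats::rlnorm(n, p$level_meanlog, p$level_sdlog),
            p$level_min), p$level_max)
}

# UTR length mixture: leaderless uniform 0..8, long log-normal clipped to
# 50..300, short log-normal clipped to 9..49 with its location chosen so
# the overall median hits utr_median
draw_utr_lengths <- function(n, p) {
  # stratified class quotas: the configured fractions are planted exactly
  # (up to rounding), not merely in expectation
  n_lead <- round(p$leaderless_fraction * n)
  n_long <- round(p$long_utr_fraction * n)
  cls <- shuffle(c(rep("leaderless", n_lead), rep("long", n_long),
                   rep("short", n - n_lead - n_long)))
  len <- integer(n)
  nl <- sum(cls == "leaderless")
  len[cls == "leaderless"] <- sample(0:8, nl, replace = TRUE)
  # aim the population median squarely at utr_median: the short component
  # is placed so P(UTR <= utr_median) is just above 1/2 and
  # P(UTR <= utr_median - 1) just below it
  q_short <- (0.525 - p$leaderless_fraction) /
    max(1 - p$leaderless_fraction - p$long_utr_fraction, 1e-9)
  q_short <- min(max(q_short, 0.05), 0.95)
  ml_short <- log(p$utr_median + 0.5) - 0.45 * stats::qnorm(q_short)
  ns <- sum(cls == "short")
  len[cls == "short"] <- pmin(pmax(round(
    stats::rlnorm(ns, ml_short, 0.45)), 9L), 49L)
  nlong <- sum(cls == "long")
  len[cls == "long"] <- pmin(pmax(round(
    stats::rlnorm(nlong, log(p$long_utr_median), 0.45)), 50L), 300L)
  list(lengths = len, classes = cls)
}

rbs_instance <- function() {
  paste0("GG", sample(c("A", "G", "T"), 1L), "G",
         sample(c("A", "G"), 1L), sample(c("A", "G", "T"), 1L))
}

# --- cassette construction (all coordinates in transcription direction) -

build_gene_plan <- function(i, initial, utr_len, utr_class, mis_offset,
                            rbs, p) {
  n_codons <- sample(152:400, 1L)
  list(initial = initial, utr = if (initial) utr_len else NA_integer_,
       utr_class = if (initial) utr_class else NA_character_,
       n_codons = n_codons,
       mis_offset = mis_offset,   # NA or 2/3 codons to the true ATG
       rbs = rbs)                 # NULL or list(spacer, seq)
}

# sequence and local feature table of one gene in transcription direction
render_gene <- function(plan, p) {
  n <- plan$n_codons
  early <- min(n - 2L, 34L)
  excl <- c(rep(TRUE, early), rep(FALSE, n - 2L - early))
  body <- random_codons(n - 2L, p$gc_coding, excl)
  start_codon <- "ATG"
  if (!is.na(plan$mis_offset)) {
    start_codon <- "GTG"
    m <- plan$mis_offset
    if (m == 3L) body[1L] <- paste0("GA", sample(c("A","C","G","T"), 1L))
    body[m] <- "ATG"  # true start, in frame, m codons past the GTG
  }
  stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)
  cds <- paste0(start_codon, paste(body, collapse = ""), stop_codon)
  utr_seq <- ""
  if (isTRUE(plan$initial) && plan$utr > 0L) {
    gc <- if (identical(plan$utr_class, "long")) p$gc_long_utr
      else p$gc_intergenic
    utr_seq <- random_dna(plan$utr, gc)
    if (!is.na(plan$mis_offset)) {
      # RBS for the true ATG overlaps the annotated GTG; the part that
      # falls in the UTR is fixed here (GGAG|GTG... or G|GTG|GA...)
      u <- plan$utr
      if (plan$mis_offset == 2L)
        substr(utr_seq, u - 3L, u) <- "GGAG"
      else
        substr(utr_seq, u, u) <- "G"
    } else if (!is.null(plan$rbs)) {
      u <- plan$utr; w <- 6L; sp <- plan$rbs$spacer
      substr(utr_seq, u - sp - w + 1L, u - sp) <- plan$rbs$seq
    }
  }
  list(seq = paste0(utr_seq, cds), utr_nchar = nchar(utr_seq),
       cds_len = nchar(cds))
}

#' Generate a synthetic genome, annotation and ground truth
#'
#' Lays out transcription units on both strands with promoter pads,
#' plants a primary TSS (with BRE/TATA) for every TU, secondary,
#' internal, antisense and orphan TSS, RBS hexamers, start-codon
#' mis-annotations, processing sites, and per-TU per-condition expression
#' levels, and returns everything needed to simulate coverage plus the
#' ground-truth ledger the tests assert against.
#'
#' @param params A [sim_params()] object.
#' @return Object of class `tss_simulation`: list with `annotation` (a
#'   `genome_annotation`), `truth` (list: `tss`, `motifs`,
#'   `processing`, `misannotations`, `expression`, `tu_map`,
#'   `switch_up`, `switch_down`) and `params`.
#' @export
simulate_genome <- function(params = sim_params()) {
  p <- params
  with_seed(p$seed, simulate_genome_impl(p))
}

simulate_genome_impl <- function(p) {
  n <- p$n_genes
  # --- TU structure ----------------------------------------------------
  sizes <- integer(0)
  while (sum(sizes) < n)
    sizes <- c(sizes, sample(seq_along(p$operon_size_probs), 1L,
                             prob = p$operon_size_probs))
  sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])
  sizes <- sizes[sizes > 0L]
  n_tu <- length(sizes)
  tu_id <- sprintf("TU%04d", seq_len(n_tu))
  gene_tu <- rep(seq_len(n_tu), sizes)
  locus <- sprintf("SYN%04d", seq_len(n))
  initial <- !duplicated(gene_tu)

  # --- UTR mixture and mis-annotations over TU-initial genes -----------
  utr <- draw_utr_lengths(n_tu, p)
  mis_k <- min(p$misannotation_count, n_tu)
  lead_idx <- which(utr$classes == "leaderless")
  mis_tu <- head(shuffle(lead_idx), mis_k)
  if (length(mis_tu) < mis_k) {
    extra <- head(shuffle(setdiff(which(utr$lengths <= 49L), mis_tu)),
                  mis_k - length(mis_tu))
    utr$classes[extra] <- "leaderless"
    mis_tu <- c(mis_tu, extra)
  }
  utr$lengths[mis_tu] <- sample(4:8, length(mis_tu), replace = TRUE)
  utr$classes[mis_tu] <- "leaderless"
  mis_offset_tu <- setNames(rep(NA_integer_, n_tu), tu_id)
  mis_offset_tu[mis_tu] <- sample(2:3, length(mis_tu), replace = TRUE)

  # --- RBS planting: quota over all mRNAs ------------------------------
  # the configured fraction is of all mRNAs; only UTRs of >= 10 nt can
  # hold a hexamer at the minimum 4 nt spacer, so the quota is filled
  # from those (mis-annotated genes carry their own RBS at the true ATG)
  rbs_tu <- vector("list", n_tu)
  eligible <- which(utr$lengths >= 10L & is.na(mis_offset_tu))
  n_rbs <- min(round(p$rbs_fraction * n_tu), length(eligible))
  for (t in head(shuffle(eligible), n_rbs)) {
    u <- utr$lengths[t]
    sp <- sample1(4:min(12L, u - 6L))
    rbs_tu[[t]] <- list(spacer = sp, seq = rbs_instance())
  }

  # --- per-gene plans and cassettes ------------------------------------
  plans <- vector("list", n)
  for (g in seq_len(n)) {
    t <- gene_tu[g]
    plans[[g]] <- build_gene_plan(
      g, initial[g],
      utr$lengths[t], utr$classes[t],
      if (initial[g]) mis_offset_tu[t] else NA_integer_,
      if (initial[g]) rbs_tu[[t]] else NULL, p)
  }

  tu_strand <- sample(c("+", "-"), n_tu, replace = TRUE)
  # promoter motif quotas: the configured fractions are planted exactly
  has_tata <- shuffle(seq_len(n_tu) <= round(p$tata_fraction * n_tu))
  has_bre <- shuffle(seq_len(n_tu) <= round(p$bre_fraction * n_tu))
  # levels & silencing
  expr <- matrix(0, n_tu, length(p$conditions),
                 dimnames = list(tu_id, p$conditions))
  base_lvl <- draw_levels(n_tu, p)
  for (ci in seq_along(p$conditions)) {
    cond <- p$conditions[ci]
    silent <- shuffle(seq_len(n_tu) <=
                        round(p$silent_fractions[[cond]] * n_tu))
    expr[, ci] <- ifelse(silent, 0, base_lvl)
  }
  dead <- rowSums(expr > 0) == 0L
  if (any(dead)) {  # every TU stays detectable in >= 1 condition
    wake <- sample(seq_along(p$conditions), sum(dead), replace = TRUE)
    expr[cbind(which(dead), wake)] <- base_lvl[dead]
  }
  switch_up <- switch_down <- NA_character_
  if (all(c("P_exp", "PS") %in% p$conditions)) {
    multi <- which(sizes >= 2L)
    if (length(multi) >= 2L) {
      sw <- sample(multi, 2L)
      switch_up <- tu_id[sw[1L]]; switch_down <- tu_id[sw[2L]]
      hi <- p$level_max; lo <- p$level_min
      expr[sw[1L], ] <- ifelse(p$conditions == "PS", hi,
                               ifelse(p$conditions == "P_exp", lo,
                                      ifelse(p$conditions == "S_exp",
                                             4, 0)))
      expr[sw[2L], ] <- ifelse(p$conditions == "P_exp", hi,
                               ifelse(p$conditions == "PS", lo,
                                      ifelse(p$conditions == "S_exp",
                                             4, 0)))
    }
  }

  # --- assemble the genome left to right -------------------------------
  blocks <- character(0)
  cursor <- 0L
  feats <- list(); tss <- list(); motifs <- list(); mis <- list()
  add_feat <- function(lt, s, e, strand)
    feats[[length(feats) + 1L]] <<- data.frame(
      locus_tag = lt, seqid = "synchr", start = s, end = e,
      strand = strand, kind = "CDS", stringsAsFactors = FALSE)
  push <- function(seq) {
    blocks[[length(blocks) + 1L]] <<- seq
    cursor <<- cursor + nchar(seq)
  }
  desert_after <- sample(seq_len(n_tu), min(p$n_otss, n_tu))
  otss <- list()
  push(random_dna(200L, p$gc_intergenic))
  gene_ptr <- 1L
  for (t in seq_len(n_tu)) {
    strand <- tu_strand[t]
    members <- which(gene_tu == t)
    rendered <- lapply(plans[members], render_gene, p = p)
    gaps <- c(0L, sample(5:40, length(members) - 1L, replace = TRUE))
    # cassette in transcription direction
    cass <- character(0); cpos <- 0L
    gene_coords <- list()
    pad_seq <- random_dna(PROMOTER_PAD, p$gc_intergenic)
    # promoter: TATA and BRE 3' offsets relative to the TSS
    t_off <- as.integer(round(min(
      max(rnorm(1, p$tata_offset_median, p$offset_sd),
          p$tata_offset_median - 3 * p$offset_sd),
      p$tata_offset_median + 3 * p$offset_sd)))
    b_off <- t_off + (p$bre_offset_median - p$tata_offset_median)
    tw <- nchar(p$tata_consensus); bw <- nchar(p$bre_consensus)
    tss_cass <- PROMOTER_PAD + 1L
    plant <- list()
    # a 3' offset of k means the motif's last base sits k bp upstream of
    # the TSS base: cassette position (PAD + 1) - k
    if (has_tata[t]) {
      inst <- mutate_consensus(p$tata_consensus, p$motif_match_prob)
      s0 <- PROMOTER_PAD + 2L - t_off - tw
      substr(pad_seq, s0, s0 + tw - 1L) <- inst
      plant[[length(plant) + 1L]] <- list(kind = "TATA", cs = s0,
                                          ce = s0 + tw - 1L,
                                          seq = inst, offset = t_off)
    }
    if (has_bre[t]) {
      inst <- mutate_consensus(p$bre_consensus, p$motif_match_prob)
      s0 <- PROMOTER_PAD + 2L - b_off - bw
      substr(pad_seq, s0, s0 + bw - 1L) <- inst
      plant[[length(plant) + 1L]] <- list(kind = "BRE", cs = s0,
                                          ce = s0 + bw - 1L,
                                          seq = inst, offset = b_off)
    }
    cass <- pad_seq; cpos <- PROMOTER_PAD
    for (k in seq_along(members)) {
      if (gaps[k] > 0L) {
        cass <- paste0(cass, random_dna(gaps[k], p$gc_intergenic))
        cpos <- cpos + gaps[k]
      }
      r <- rendered[[k]]
      cds_start_cass <- cpos + r$utr_nchar + 1L
      cass <- paste0(cass, r$seq)
      cpos <- cpos + nchar(r$seq)
      gene_coords[[k]] <- c(cds_start_cass, cpos)
    }
    block_start <- cursor + 1L
    block_len <- nchar(cass)
    to_genome <- function(cp) if (strand == "+") block_start + cp - 1L
      else block_start + block_len - cp
    push(if (strand == "+") cass else revcomp_chr(cass))
    # features
    for (k in seq_along(members)) {
      g <- members[k]
      cs <- gene_coords[[k]][1L]; ce <- gene_coords[[k]][2L]
      g1 <- to_genome(cs); g2 <- to_genome(ce)
      add_feat(locus[g], min(g1, g2), max(g1, g2), strand)
    }
    # primary TSS of the TU
    lead_gene <- locus[members[1L]]
    tss_pos <- to_genome(tss_cass)
    tss[[length(tss) + 1L]] <- data.frame(
      seqid = "synchr", pos = tss_pos, strand = strand, class = "pTSS",
      locus_tag = lead_gene, tu = tu_id[t],
      level = NA_real_, depth_factor = 1,
      terminus = NA_character_, stringsAsFactors = FALSE)
    for (pl in plant)
      motifs[[length(motifs) + 1L]] <- data.frame(
        kind = pl$kind, seqid = "synchr",
        start = min(to_genome(pl$cs), to_genome(pl$ce)),
        end = max(to_genome(pl$cs), to_genome(pl$ce)),
        strand = strand, seq = pl$seq, offset = pl$offset,
        anchor_pos = tss_pos, stringsAsFactors = FALSE)
    # planted RBS bookkeeping
    if (!is.null(rbs_tu[[t]])) {
      sp <- rbs_tu[[t]]$spacer
      e_cass <- tss_cass + u - sp - 1L      # RBS 3' end in cassette
      s_cass <- e_cass - 5L
      motifs[[length(motifs) + 1L]] <- data.frame(
        kind = "RBS", seqid = "synchr",
        start = min(to_genome(s_cass), to_genome(e_cass)),
        end = max(to_genome(s_cass), to_genome(e_cass)),
        strand = strand, seq = rbs_tu[[t]]$seq, offset = sp,
        anchor_pos = to_genome(tss_cass + u), stringsAsFactors = FALSE)
    }
    if (!is.na(mis_offset_tu[t])) {
      m <- mis_offset_tu[t]
      cds_start <- gene_coords[[1L]][1L]
      mis[[length(mis) + 1L]] <- data.frame(
        locus_tag = lead_gene,
        annotated_start = to_genome(cds_start),
        true_start = to_genome(cds_start + 3L * m),
        offset_codons = m, utr_annotated = u,
        stringsAsFactors = FALSE)
    }
    push(random_dna(sample(80:200, 1L), p$gc_intergenic))
    if (t %in% desert_after) {
      otss[[length(otss) + 1L]] <- data.frame(
        seqid = "synchr", pos = cursor + 400L,
        strand = sample(c("+", "-"), 1L), class = "oTSS",
        locus_tag = NA_character_, tu = NA_character_,
        level = NA_real_, depth_factor = p$aux_depth_factor,
        terminus = NA_character_, stringsAsFactors = FALSE)
      push(random_dna(800L, p$gc_intergenic))
    }
    gene_ptr <- gene_ptr + length(members)
  }
  genome <- Biostrings::DNAStringSet(paste(blocks, collapse = ""))
  names(genome) <- "synchr"
  feats <- do.call(rbind, feats)
  tss <- do.call(rbind, c(tss, otss))

  # --- internal and antisense TSS, planted by genome coordinates -------
  too_close <- function(pos, strand, df)
    any(df$strand == strand & abs(df$pos - pos) <= 4L)
  gene_lvl_tu <- tu_id[gene_tu]
  scp <- ifelse(feats$strand == "+", feats$start, feats$end)
  stp <- ifelse(feats$strand == "+", feats$end, feats$start)
  glen0 <- sum(nchar(blocks))
  # secondary TSS: each 5'-UTR is an independent draw from the same
  # mixture, so the combined pTSS+sTSS length distribution keeps the
  # configured median and class fractions
  stss_tu <- which(runif(n_tu) < p$stss_prob)
  d_stss <- draw_utr_lengths(length(stss_tu), p)$lengths  # one batch,
                                                  # quota preserved
  for (k in seq_along(stss_tu)) {
    t <- stss_tu[k]
    lead <- locus[which(gene_tu == t)[1L]]
    g <- which(feats$locus_tag == lead)
    u <- utr$lengths[t]
    d_s <- d_stss[k]
    # keep the secondary peak clear of the primary without redrawing the
    # class: nudge away by the cluster-separation margin
    if (abs(d_s - u) < 5L) d_s <- max(0L, d_s + if (d_s >= u) 5L else -5L)
    if (abs(d_s - u) < 5L) next
    pos <- if (feats$strand[g] == "+") scp[g] - d_s else scp[g] + d_s
    if (pos < 1L || pos > glen0) next
    if (too_close(pos, feats$strand[g], tss)) next
    tss <- rbind(tss, data.frame(
      seqid = "synchr", pos = pos, strand = feats$strand[g],
      class = "sTSS", locus_tag = lead, tu = tu_id[t],
      level = NA_real_, depth_factor = p$stss_rel_height,
      terminus = NA_character_, stringsAsFactors = FALSE))
  }
  n_itss <- round(p$itss_per_gene * n)
  extra <- list()
  add_tss <- function(pos, strand, class, lt, tu, depth_factor,
                      terminus) {
    row <- data.frame(seqid = "synchr", pos = pos, strand = strand,
                      class = class, locus_tag = lt, tu = tu,
                      level = NA_real_, depth_factor = depth_factor,
                      terminus = terminus, stringsAsFactors = FALSE)
    tss <<- rbind(tss, row)
  }
  for (i in seq_len(n_itss)) {
    for (try in 1:20) {
      g <- sample(n, 1L)
      len <- feats$end[g] - feats$start[g] + 1L
      d <- sample(120:(len - 10L), 1L)
      pos <- if (feats$strand[g] == "+") feats$start[g] + d
        else feats$end[g] - d
      if (!too_close(pos, feats$strand[g], tss)) {
        add_tss(pos, feats$strand[g], "iTSS", locus[g], gene_lvl_tu[g],
                p$aux_depth_factor, NA_character_)
        break
      }
    }
  }
  n_atss <- round(p$atss_per_gene * n)
  # terminus association is a planted quota, not a Bernoulli draw
  near_term <- shuffle(seq_len(n_atss) <=
                         round(p$atss_terminus_fraction * n_atss))
  for (i in seq_len(n_atss)) {
    for (try in 1:20) {
      g <- sample(n, 1L)
      a_strand <- if (feats$strand[g] == "+") "-" else "+"
      len <- feats$end[g] - feats$start[g] + 1L
      if (near_term[i]) {
        term <- sample(c("5p", "3p"), 1L)
        anchor <- if (term == "5p") scp[g] else stp[g]
        delta <- if (term == "5p")
          sample(-100:p$terminus_window, 1L)
        else sample(-p$terminus_window:100, 1L)
        pos <- if (feats$strand[g] == "+") anchor + delta
          else anchor - delta
      } else {
        term <- "none"
        if (len < 2L * (p$terminus_window + 1L) + 20L) next
        d <- sample((p$terminus_window + 1L):
                      (len - p$terminus_window - 2L), 1L)
        pos <- if (feats$strand[g] == "+") feats$start[g] + d
          else feats$end[g] - d
      }
      glen <- Biostrings::width(genome)[1L]
      if (pos < 1L || pos > glen) next
      if (!too_close(pos, a_strand, tss)) {
        add_tss(pos, a_strand, "aTSS", locus[g], NA_character_,
                p$aux_depth_factor, term)
        break
      }
    }
  }
  # constitutive levels for TSS not tied to a TU program
  own <- is.na(tss$tu)
  tss$level[own] <- draw_levels(sum(own), p)

  # --- processing sites ------------------------------------------------
  glen <- Biostrings::width(genome)[1L]
  n_proc <- round(p$processing_sites_per_kb * glen / 1000)
  proc <- list()
  for (i in seq_len(n_proc)) {
    for (try in 1:20) {
      g <- sample(n, 1L)
      pos <- sample(feats$start[g]:feats$end[g], 1L)
      if (!too_close(pos, feats$strand[g], tss)) {
        proc[[length(proc) + 1L]] <- data.frame(
          seqid = "synchr", pos = pos, strand = feats$strand[g],
          host = locus[g], tu = gene_lvl_tu[g],
          stringsAsFactors = FALSE)
        break
      }
    }
  }
  proc <- if (length(proc)) do.call(rbind, proc)
    else data.frame(seqid = character(0), pos = integer(0),
                    strand = character(0), host = character(0),
                    tu = character(0), stringsAsFactors = FALSE)

  # expected treated peak depth per condition
  tu_idx <- match(tss$tu, rownames(expr))
  for (cond in p$conditions) {
    lvl <- ifelse(is.na(tu_idx), tss$level, expr[tu_idx, cond])
    tss[[paste0("exp_", cond)]] <- p$depth * tss$depth_factor * lvl
  }
  tss <- tss[order(tss$pos, tss$strand), , drop = FALSE]
  rownames(tss) <- NULL
  tss$tss_id <- sprintf("TSS%05d", seq_len(nrow(tss)))

  operons <- split(locus, gene_lvl_tu)
  operons <- operons[vapply(operons, length, integer(1)) >= 1L]
  annotation <- genome_annotation(genome, feats, operons)
  mis <- if (length(mis)) do.call(rbind, mis)
    else data.frame(locus_tag = character(0),
                    annotated_start = integer(0),
                    true_start = integer(0), offset_codons = integer(0),
                    utr_annotated = integer(0), stringsAsFactors = FALSE)
  structure(list(
    annotation = annotation,
    truth = list(tss = tss,
                 motifs = do.call(rbind, motifs),
                 processing = proc,
                 misannotations = mis,
                 expression = expr,
                 tu_map = setNames(gene_lvl_tu, locus),
                 utr_lengths = setNames(utr$lengths, tu_id),
                 switch_up = switch_up, switch_down = switch_down),
    params = p), class = "tss_simulation")
}

#' @export
print.tss_simulation <- function(x, ...) {
  cat("tss_simulation:", nrow(x$annotation$features), "genes,",
      nrow(x$truth$tss), "planted TSS,",
      Biostrings::width(x$annotation$genome)[1L], "bp genome\n")
  invisible(x)
}

# distribute n reads at pos with +-1 smear
smear_counts <- function(vec, pos, n, smear_prob) {
  if (n == 0L) return(vec)
  k <- stats::rmultinom(1L, n, c(smear_prob / 2, 1 - smear_prob,
                                 smear_prob / 2))[, 1L]
  at <- pos + (-1:1)
  ok <- at >= 1L & at <= length(vec)
  vec[at[ok]] <- vec[at[ok]] + k[ok]
  vec
}

#' Simulate a 5'-end coverage track for one library
#'
#' Treated (TEX+) libraries carry the planted TSS peaks at full depth;
#' untreated libraries carry them attenuated
#' (`untreated_primary_fraction`) plus processing-site peaks and the full
#' complement of gene-body 5' ends, of which TEX digestion leaves only
#' `treated_body_fraction` in treated libraries. Uniform Poisson
#' background is added to both strands.
#'
#' @param sim A `tss_simulation` from [simulate_genome()].
#' @param condition Condition name (must be in `params$conditions`).
#' @param treated Simulate the TEX-treated library?
#' @param seed Integer seed for this track.
#' @return A `coverage_track`.
#' @export
simulate_coverage <- function(sim, condition, treated, seed) {
  p <- sim$params
  if (!condition %in% p$conditions)
    stop("unknown condition: ", condition)
  with_seed(seed, simulate_coverage_impl(sim, condition, treated))
}

simulate_coverage_impl <- function(sim, condition, treated) {
  p <- sim$params
  glen <- Biostrings::width(sim$annotation$genome)[1L]
  fwd <- integer(glen); rev <- integer(glen)
  truth <- sim$truth
  expcol <- paste0("exp_", condition)
  # planted TSS peaks
  for (i in seq_len(nrow(truth$tss))) {
    lambda <- truth$tss[[expcol]][i]
    if (!treated) lambda <- lambda * p$untreated_primary_fraction
    if (lambda <= 0) next
    nreads <- rpois(1L, lambda)
    if (truth$tss$strand[i] == "+")
      fwd <- smear_counts(fwd, truth$tss$pos[i], nreads, p$smear_prob)
    else
      rev <- smear_counts(rev, truth$tss$pos[i], nreads, p$smear_prob)
  }
  # processing sites: suppressed by TEX
  if (!treated && nrow(truth$processing)) {
    lvl <- truth$expression[truth$processing$tu, condition]
    for (i in seq_len(nrow(truth$processing))) {
      lambda <- p$processed_depth * lvl[i] / 2
      if (lambda <= 0) next
      nreads <- rpois(1L, lambda)
      if (truth$processing$strand[i] == "+")
        fwd <- smear_counts(fwd, truth$processing$pos[i], nreads,
                            p$smear_prob)
      else
        rev <- smear_counts(rev, truth$processing$pos[i], nreads,
                            p$smear_prob)
    }
  }
  # gene-body 5' ends from fragmentation/processing
  ft <- sim$annotation$features
  body_rate <- p$body_read_rate *
    (if (treated) p$treated_body_fraction else 1)
  lvl_gene <- truth$expression[truth$tu_map[ft$locus_tag], condition]
  for (g in seq_len(nrow(ft))) {
    if (lvl_gene[g] <= 0) next
    span <- ft$start[g]:ft$end[g]
    reads <- rpois(length(span), body_rate * lvl_gene[g])
    if (ft$strand[g] == "+") fwd[span] <- fwd[span] + reads
    else rev[span] <- rev[span] + reads
  }
  # uniform background
  fwd <- fwd + rpois(glen, p$noise)
  rev <- rev + rpois(glen, p$noise)
  coverage_track(
    setNames(list(list(fwd = as.integer(fwd), rev = as.integer(rev))),
             names(sim$annotation$genome)),
    library_id = paste0(condition, if (treated) "_TEX" else "_noTEX"),
    condition = condition, treated = treated)
}

#' Simulate the full set of treated/untreated tracks
#'
#' One TEX-treated and one untreated track per condition, with track
#' seeds derived deterministically from `params$seed`.
#'
#' @param sim A `tss_simulation`.
#' @return List with named lists `treated` and `untreated`, keyed by
#'   condition.
#' @export
simulate_tracks <- function(sim) {
  p <- sim$params
  treated <- untreated <- list()
  for (ci in seq_along(p$conditions)) {
    cond <- p$conditions[ci]
    treated[[cond]] <- simulate_coverage(sim, cond, TRUE,
                                         p$seed * 1000L + 2L * ci)
    untreated[[cond]] <- simulate_coverage(sim, cond, FALSE,
                                           p$seed * 1000L + 2L * ci + 1L)
  }
  list(treated = treated, untreated = untreated)
}

#' Write the planted-TSS ground truth as TSV
#'
#' One row per planted TSS with class, associated locus tag,
#' transcription unit and per-condition expected peak depths;
#' round-trippable with [read_truth()].
#'
#' @param truth The `truth` element of a `tss_simulation` (or the
#'   simulation itself).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  if (inherits(truth, "tss_simulation")) truth <- truth$truth
  write.table(truth$tss, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a planted-TSS ground-truth table
#'
#' @param path Path written by [write_truth()].
#' @return data.frame of planted TSS.
#' @export
read_truth <- function(path) {
  read.delim(path, header = TRUE, stringsAsFactors = FALSE,
             na.strings = "NA")
}
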