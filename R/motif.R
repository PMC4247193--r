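#' Motif discovery parameters
#'
#' Widths of the promoter and RBS motifs searched in TSS-anchored windows,
#' EM settings, and the bit-score threshold above which a window counts as
#' carrying the motif. The TATA box (default width 8) and the
#' transcription-factor-B recognition element (BRE, default width 7)
#' are the archaeal core promoter elements expected upstream of a TSS.
#'
#' @param upstream Window length upstream of the anchor; the scanned
#'   window is `-upstream..0` inclusive of the anchor base (default 50).
#' @param tata_width,bre_width,rbs_width Motif widths in nt.
#' @param n_restarts EM restarts, best likelihood wins (default 10).
#' @param max_iter Maximum EM iterations per restart (default 200).
#' @param tol Log-likelihood convergence tolerance (default 1e-6).
#' @param pseudocount Per-base pseudocount in the M-step (default 0.25).
#' @param hit_threshold Log-odds bits above which the best site in a
#'   window counts as a motif occurrence (default 3; promoter motifs in
#'   AT-rich genomes score against a background that partly mimics them,
#'   so a permissive threshold recovers the planted fraction best).
#' @return Named list of motif parameters.
#' @export
motif_params <- function(upstream = 50, tata_width = 8, bre_width = 7,
                         rbs_width = 6, n_restarts = 10, max_iter = 200,
                         tol = 1e-6, pseudocount = 0.25,
                         hit_threshold = 3) {
  stopifnot(upstream > 0, tata_width >= 4, bre_width >= 4,
            rbs_width >= 4, n_restarts >= 1)
  list(upstream = upstream, tata_width = tata_width,
       bre_width = bre_width, rbs_width = rbs_width,
       n_restarts = n_restarts, max_iter = max_iter, tol = tol,
       pseudocount = pseudocount, hit_threshold = hit_threshold)
}

BASES <- c("A", "C", "G", "T")

encode_seqs <- function(seqs) {
  mat <- t(vapply(strsplit(seqs, ""), function(x)
    match(x, BASES), integer(nchar(seqs[1L]))))
  if (anyNA(mat)) stop("sequences must be over A/C/G/T for motif work")
  mat
}

#' Extract promoter windows upstream of TSS
#'
#' Strand-aware windows covering `-upstream..0` relative to each TSS (the
#' TSS base is the last position), reverse-complemented on the minus
#' strand so all windows read in the direction of transcription. TSS too
#' close to a replicon edge for a full window are excluded and reported
#' in the `excluded` attribute.
#'
#' @param tss data.frame with `seqid`, `pos`, `strand` (one row per unique
#'   TSS).
#' @param genome A [Biostrings::DNAStringSet].
#' @param upstream Window length upstream of the TSS (default 50).
#' @return Named character vector of windows of length `upstream + 1`,
#'   named `seqid:pos:strand`; attribute `excluded` lists skipped
#'   anchors.
#' @export
extract_windows <- function(tss, genome, upstream = 50) {
  rlen <- setNames(Biostrings::width(genome), names(genome))
  lo <- ifelse(tss$strand == "+", tss$pos - upstream, tss$pos)
  hi <- ifelse(tss$strand == "+", tss$pos, tss$pos + upstream)
  ok <- lo >= 1L & hi <= rlen[tss$seqid]
  out <- character(sum(ok))
  idx <- which(ok)
  for (k in seq_along(idx)) {
    i <- idx[k]
    out[k] <- subseq_chr(genome, tss$seqid[i], lo[i], hi[i],
                         tss$strand[i])
  }
  names(out) <- paste(tss$seqid[idx], tss$pos[idx], tss$strand[idx],
                      sep = ":")
  attr(out, "excluded") <- paste(tss$seqid[!ok], tss$pos[!ok],
                                 tss$strand[!ok], sep = ":")
  out
}

site_loglik <- function(enc, logpwm, logbg) {
  n <- nrow(enc); L <- ncol(enc); w <- ncol(logpwm)
  J <- L - w + 1L
  bg_pos <- matrix(logbg[enc], n, L)
  bg_cum <- t(apply(bg_pos, 1L, cumsum))
  bg_tot <- bg_cum[, L]
  ll <- matrix(0, n, J)
  for (j in seq_len(J)) {
    m <- 0
    for (k in seq_len(w)) m <- m + logpwm[cbind(enc[, j + k - 1L], k)]
    span <- bg_cum[, j + w - 1L] - if (j == 1L) 0 else bg_cum[, j - 1L]
    ll[, j] <- bg_tot - span + m
  }
  ll
}

em_run <- function(enc, w, bg, init_pwm, max_iter, tol, pseudocount) {
  n <- nrow(enc); L <- ncol(enc); J <- L - w + 1L
  pwm <- init_pwm
  logbg <- log(bg)
  ll_old <- -Inf
  loglik_trace <- numeric(0)
  post <- NULL
  for (iter in seq_len(max_iter)) {
    ll <- site_loglik(enc, log(pwm), logbg)
    mx <- apply(ll, 1L, max)
    p <- exp(ll - mx)
    rs <- rowSums(p)
    post <- p / rs
    loglik <- sum(mx + log(rs) - log(J))  # uniform site prior
    loglik_trace <- c(loglik_trace, loglik)
    counts <- matrix(pseudocount, 4L, w, dimnames = list(BASES, NULL))
    for (j in seq_len(J)) {
      pj <- post[, j]
      for (k in seq_len(w)) {
        b <- enc[, j + k - 1L]
        counts[, k] <- counts[, k] +
          vapply(1:4, function(bb) sum(pj[b == bb]), numeric(1))
      }
    }
    pwm <- sweep(counts, 2L, colSums(counts), "/")
    if (is.finite(ll_old) && abs(loglik - ll_old) < tol) break
    ll_old <- loglik
  }
  list(pwm = pwm, loglik = loglik_trace[length(loglik_trace)],
       loglik_trace = loglik_trace, post = post)
}

#' Discover one motif by one-occurrence-per-sequence EM
#'
#' Expectation-maximisation under the OOPS model: every sequence carries
#' exactly one motif site at an unknown position; the E-step computes the
#' posterior over site positions under the current position weight matrix
#' (PWM) against a 0-order background, the M-step re-estimates the PWM
#' from expected counts with pseudocounts. The best of `n_restarts`
#' randomly seeded runs (by final log-likelihood) is returned;
#' deterministic given `seed`.
#'
#' @param seqs Character vector of equal-length sequences (each at least
#'   `width` nt).
#' @param width Motif width.
#' @param params [motif_params()] (restarts, iterations, tolerance,
#'   pseudocount).
#' @param seed Integer seed for the restarts.
#' @return Object of class `motif_model`: list with `width`, `pwm` (4 x
#'   width column-stochastic matrix, rows A/C/G/T), `background`,
#'   `loglik`, `loglik_trace`, `consensus`, and `sites` (data.frame of
#'   each sequence's maximum-posterior site: `anchor`, `offset`, `site`,
#'   `posterior`).
#' @export
find_motif_em <- function(seqs, width, params = motif_params(),
                          seed = 1) {
  if (length(seqs) == 0L) stop("no sequences")
  if (any(nchar(seqs) < width))
    stop("sequence shorter than motif width: ",
         names(seqs)[nchar(seqs) < width][1L])
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must have equal length")
  enc <- encode_seqs(seqs)
  bg <- as.numeric(table(factor(BASES[enc], levels = BASES)))
  bg <- (bg + 1) / sum(bg + 1)
  names(bg) <- BASES
  J <- ncol(enc) - width + 1L
  best <- NULL
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  for (r in seq_len(params$n_restarts)) {
    i <- sample.int(nrow(enc), 1L); j <- sample.int(J, 1L)
    seed_site <- enc[i, j:(j + width - 1L)]
    init <- matrix(rep(bg, width), 4L, width,
                   dimnames = list(BASES, NULL))
    init <- init * 0.5
    init[cbind(seed_site, seq_len(width))] <-
      init[cbind(seed_site, seq_len(width))] + 0.5
    init <- sweep(init, 2L, colSums(init), "/")
    run <- em_run(enc, width, bg, init, params$max_iter, params$tol,
                  params$pseudocount)
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  # column-shift refinement: EM can settle one column off the optimal
  # register (a flank column traded for an informative edge column);
  # restart from +-1/+-2 shifted PWMs and keep the best likelihood
  for (shift in c(-2L, -1L, 1L, 2L)) {
    pwm0 <- best$pwm
    shifted <- matrix(rep(bg, width), 4L, width,
                      dimnames = list(BASES, NULL))
    src <- seq_len(width) - shift
    ok <- src >= 1L & src <= width
    shifted[, ok] <- pwm0[, src[ok]]
    run <- em_run(enc, width, bg, shifted, params$max_iter,
                  params$tol, params$pseudocount)
    if (run$loglik > best$loglik + 1e-9) best <- run
  }
  offs <- apply(best$post, 1L, which.max)
  sites <- data.frame(
    anchor = if (is.null(names(seqs))) as.character(seq_along(seqs))
      else names(seqs),
    offset = offs,
    site = substr(seqs, offs, offs + width - 1L),
    posterior = best$post[cbind(seq_len(nrow(enc)), offs)],
    stringsAsFactors = FALSE)
  structure(list(width = width, pwm = best$pwm, background = bg,
                 loglik = best$loglik,
                 loglik_trace = best$loglik_trace,
                 consensus = paste(BASES[apply(best$pwm, 2L, which.max)],
                                   collapse = ""),
                 sites = sites),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("motif_model: width", x$width, "consensus", x$consensus,
      "logLik", format(x$loglik, digits = 6), "\n")
  invisible(x)
}

#' Scan a sequence with a PWM
#'
#' Log-odds score (bits) of the PWM against its background at every
#' offset of the sense strand; offsets scoring at least `threshold_bits`
#' are reported.
#'
#' @param seq A single sequence (character).
#' @param motif A `motif_model` (or list with `pwm` and `background`).
#' @param threshold_bits Minimum score in bits (default `-Inf`, all
#'   offsets).
#' @return data.frame with `offset` (1-based) and `score` for each hit.
#' @export
scan_pwm <- function(seq, motif, threshold_bits = -Inf) {
  w <- ncol(motif$pwm)
  if (nchar(seq) < w) stop("sequence shorter than motif width")
  enc <- encode_seqs(seq)[1L, ]
  lo <- log2(motif$pwm / motif$background)
  J <- length(enc) - w + 1L
  score <- vapply(seq_len(J), function(j)
    sum(lo[cbind(enc[j:(j + w - 1L)], seq_len(w))]), numeric(1))
  hits <- which(score >= threshold_bits)
  data.frame(offset = hits, score = score[hits])
}

#' Match an IUPAC pattern against a sequence
#'
#' Reports every (possibly overlapping) offset where each base is in the
#' IUPAC code's set (e.g. `D` = A/G/T, `R` = A/G).
#'
#' @param seq A single sequence.
#' @param pattern IUPAC pattern, e.g. `"GGDGRD"`.
#' @return Integer vector of 1-based offsets (possibly empty).
#' @export
match_iupac <- function(seq, pattern) {
  codes <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
             S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
             D = "AGT", H = "ACT", V = "ACG", N = "ACGT")
  chars <- strsplit(toupper(pattern), "")[[1L]]
  if (!all(chars %in% names(codes)))
    stop("invalid IUPAC code in pattern: ",
         chars[!chars %in% names(codes)][1L])
  rx <- paste0("(?=", paste0("[", codes[chars], "]", collapse = ""),
               ")")
  m <- gregexpr(rx, toupper(seq), perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Motif-to-anchor offset distribution
#'
#' Scans every window with a PWM, keeps each window's best site, and
#' summarises the distance from the motif's 3'-most base to the anchor
#' (the TSS, the last base of the window). Windows whose best score falls
#' below the hit threshold count towards the fraction without a motif but
#' are excluded from the median and histogram.
#'
#' @param windows Character vector from [extract_windows()].
#' @param motif A `motif_model`.
#' @param threshold_bits Hit threshold in bits (default
#'   `motif_params()$hit_threshold`).
#' @return List with `n_anchors`, `n_hits`, `fraction_with_motif`,
#'   `median_offset` (bp from motif 3' end to the anchor) and `histogram`
#'   (table over offsets).
#' @export
offset_distribution <- function(windows, motif,
                                threshold_bits =
                                  motif_params()$hit_threshold) {
  L <- unique(nchar(windows))
  stopifnot(length(L) == 1L)
  w <- ncol(motif$pwm)
  best <- t(vapply(windows, function(s) {
    sc <- scan_pwm(s, motif)
    i <- which.max(sc$score)
    c(sc$offset[i], sc$score[i])
  }, numeric(2)))
  hit <- best[, 2L] >= threshold_bits
  offsets <- L - (best[hit, 1L] + w - 1L)
  list(n_anchors = length(windows), n_hits = sum(hit),
       fraction_with_motif = mean(hit),
       median_offset = if (any(hit)) median(offsets) else NA_real_,
       histogram = table(offsets))
}

#' Discover several motifs by iterative masking
#'
#' Runs [find_motif_em()] for each requested width in turn; after each
#' motif the best site of every sequence is replaced by bases drawn from
#' the background so the next run cannot rediscover it.
#'
#' @param seqs Equal-length sequences.
#' @param widths Integer vector of motif widths, searched in order.
#' @param params [motif_params()].
#' @param seed Integer seed (restarts and masking).
#' @return List of `motif_model` objects, one per width.
#' @export
find_motifs <- function(seqs, widths, params = motif_params(),
                        seed = 1) {
  out <- vector("list", length(widths))
  cur <- seqs
  for (m in seq_along(widths)) {
    out[[m]] <- find_motif_em(cur, widths[m], params,
                              seed = seed + m - 1L)
    if (m < length(widths)) {
      sites <- out[[m]]$sites
      old_seed <- get0(".Random.seed", envir = globalenv())
      set.seed(seed + 1000L + m)
      bg <- out[[m]]$background
      for (i in seq_along(cur)) {
        j <- sites$offset[i]
        repl <- paste(sample(BASES, widths[m], replace = TRUE,
                             prob = bg), collapse = "")
        substr(cur[i], j, j + widths[m] - 1L) <- repl
      }
      if (!is.null(old_seed))
        assign(".Random.seed", old_seed, envir = globalenv())
    }
  }
  out
}

#' Write a position weight matrix as text
#'
#' One row per motif position, four tab-separated columns (A, C, G, T).
#'
#' @param motif A `motif_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(motif, path) {
  df <- as.data.frame(t(motif$pwm))
  names(df) <- BASES
  write.table(format(df, digits = 6), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a position weight matrix written by [write_pwm()]
#'
#' @param path Path to the PWM text file.
#' @param background Base probabilities (default uniform).
#' @return A `motif_model` (without sites or likelihood).
#' @export
read_pwm <- function(path, background = rep(0.25, 4)) {
  df <- read.delim(path, header = TRUE)
  stopifnot(identical(names(df), BASES))
  pwm <- t(as.matrix(df))
  rownames(pwm) <- BASES
  structure(list(width = ncol(pwm), pwm = pwm,
                 background = setNames(background, BASES),
                 loglik = NA_real_,
                 consensus = paste(BASES[apply(pwm, 2L, which.max)],
                                   collapse = ""),
                 sites = NULL),
            class = "motif_model")
}
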