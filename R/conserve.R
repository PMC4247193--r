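#' Pairwise alignment parameters for sRNA conservation
#'
#' Identity-driven local alignment scoring in the style of nucleotide
#' BLAST: small positive match reward, comparable mismatch and gap
#' penalties, and an exact-word seed requirement for the heuristic path.
#'
#' @param match Match score (default +1).
#' @param mismatch Mismatch score (default -1).
#' @param gap_open Gap opening score (default -2).
#' @param gap_extend Gap extension score (default -1).
#' @param min_word Minimum exact seed length for the seeded aligner
#'   (default 10 nt).
#' @param retain_threshold Conservation value (percent) at or above which
#'   a hit is retained (default 40).
#' @param full_dp_max Sequence length below which the full
#'   Smith-Waterman is used instead of the seeded heuristic
#'   (default 2000).
#' @return Named list of alignment parameters.
#' @export
align_params <- function(match = 1, mismatch = -1, gap_open = -2,
                         gap_extend = -1, min_word = 10,
                         retain_threshold = 40, full_dp_max = 2000) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend <= 0,
            min_word >= 1)
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend, min_word = min_word,
       retain_threshold = retain_threshold, full_dp_max = full_dp_max)
}

# affine-gap Smith-Waterman over a band of subject columns; returns the
# best local score and the number of identical aligned columns on an
# optimal path
sw_align <- function(q, s, params) {
  n <- length(q); m <- length(s)
  NEG <- -1e9
  # three-state DP: M (match/mismatch), X (gap in subject), Y (gap in query)
  M <- matrix(0, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  # traceback: 0 stop, 1 diag from M, 2 from X, 3 from Y
  tb <- array(0L, dim = c(n + 1L, m + 1L, 3L))
  go <- params$gap_open; ge <- params$gap_extend
  best <- 0; bi <- 0L; bj <- 0L; bs <- 1L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (q[i] == s[j]) params$match else params$mismatch
      prev <- c(M[i, j], X[i, j], Y[i, j])
      k <- which.max(prev)
      if (prev[k] <= 0) { mv <- sub; k <- 0L }  # fresh local start
      else mv <- prev[k] + sub
      if (mv <= 0) { M[i + 1L, j + 1L] <- 0; tb[i + 1L, j + 1L, 1L] <- 0L }
      else { M[i + 1L, j + 1L] <- mv; tb[i + 1L, j + 1L, 1L] <- k }
      xo <- M[i, j + 1L] + go; xe <- X[i, j + 1L] + ge
      if (xo >= xe) { X[i + 1L, j + 1L] <- xo; tb[i + 1L, j + 1L, 2L] <- 1L }
      else { X[i + 1L, j + 1L] <- xe; tb[i + 1L, j + 1L, 2L] <- 2L }
      yo <- M[i + 1L, j] + go; ye <- Y[i + 1L, j] + ge
      if (yo >= ye) { Y[i + 1L, j + 1L] <- yo; tb[i + 1L, j + 1L, 3L] <- 1L }
      else { Y[i + 1L, j + 1L] <- ye; tb[i + 1L, j + 1L, 3L] <- 3L }
      if (M[i + 1L, j + 1L] > best) {
        best <- M[i + 1L, j + 1L]; bi <- i + 1L; bj <- j + 1L; bs <- 1L
      }
    }
  }
  if (best <= 0)
    return(list(score = 0, identical_nt = 0L, query_span = c(0L, 0L),
                subject_span = c(0L, 0L)))
  # traceback from (bi, bj), which is in state M by construction
  i <- bi; j <- bj; st <- bs; ident <- 0L
  qend <- bi - 1L; send <- bj - 1L
  repeat {
    if (st == 1L) {
      from <- tb[i, j, 1L]
      if (q[i - 1L] == s[j - 1L]) ident <- ident + 1L
      i <- i - 1L; j <- j - 1L
      if (from == 0L) break  # this cell opened the local alignment
      st <- from
    } else if (st == 2L) {
      st <- tb[i, j, 2L]; i <- i - 1L
    } else {
      st <- tb[i, j, 3L]; j <- j - 1L
    }
  }
  list(score = best, identical_nt = ident,
       query_span = c(i, qend), subject_span = c(j, send))
}

# exact shared words of length >= min_word via substring hashing
find_seeds <- function(q, s, min_word) {
  nq <- nchar(q); ns <- nchar(s)
  if (nq < min_word || ns < min_word) return(NULL)
  qw <- substring(q, 1:(nq - min_word + 1L), min_word:nq)
  sw <- substring(s, 1:(ns - min_word + 1L), min_word:ns)
  hit <- which(qw %in% sw)
  if (!length(hit)) return(NULL)
  sidx <- lapply(qw[hit], function(w) which(sw == w))
  data.frame(qpos = rep(hit, lengths(sidx)),
             spos = unlist(sidx))
}

align_one_orientation <- function(query, subject, params) {
  q <- strsplit(query, "")[[1L]]
  s <- strsplit(subject, "")[[1L]]
  if (max(length(q), length(s)) < params$full_dp_max)
    return(sw_align(q, s, params))
  seeds <- find_seeds(query, subject, params$min_word)
  if (is.null(seeds))
    return(list(score = 0, identical_nt = 0L, query_span = c(0L, 0L),
                subject_span = c(0L, 0L)))
  # extend around distinct seed diagonals within a subject window
  diags <- unique(seeds$spos - seeds$qpos)
  best <- list(score = 0, identical_nt = 0L, query_span = c(0L, 0L),
               subject_span = c(0L, 0L))
  pad <- length(q)
  for (d in diags) {
    lo <- max(1L, 1L + d - pad %/% 2L)
    hi <- min(length(s), length(q) + d + pad %/% 2L)
    res <- sw_align(q, s[lo:hi], params)
    if (res$score > best$score) {
      res$subject_span <- res$subject_span + lo - 1L
      best <- res
    }
  }
  best
}

#' Best local alignment of a query against a subject
#'
#' Smith-Waterman with affine gaps for ordinary sRNA-sized inputs, a
#' seeded heuristic (exact word of at least `min_word` nt, then local
#' extension) for long subjects. Both orientations of the subject are
#' searched; the query is never reverse-complemented so its length stays
#' the conservation denominator.
#'
#' @param query,subject Sequences over A/C/G/T.
#' @param params [align_params()].
#' @return List with `score`, `identical_nt`, `query_span`,
#'   `subject_span`, `orientation` (`"+"` or `"-"`).
#' @export
local_align <- function(query, subject, params = align_params()) {
  if (!nzchar(query) || !nzchar(subject))
    stop("empty sequence in alignment")
  query <- toupper(query); subject <- toupper(subject)
  fwd <- align_one_orientation(query, subject, params)
  rev <- align_one_orientation(query, revcomp_chr(subject), params)
  if (rev$score > fwd$score) c(rev, orientation = "-")
  else c(fwd, orientation = "+")
}

#' Percentage conservation of a small RNA
#'
#' The number of identical nucleotides in the best local alignment
#' divided by the query sRNA length, times 100. Values at or above the
#' retain threshold (default 40 percent) are flagged as retained. The
#' statistic is asymmetric: the denominator is always the query length.
#'
#' @param query,subject Sequences over A/C/G/T.
#' @param params [align_params()].
#' @param query_id,subject_id Optional identifiers for the result.
#' @return data.frame (one row): `query_id`, `subject_id`,
#'   `identical_nt`, `query_length`, `conservation_value`, `retained`,
#'   `score`, `orientation`.
#' @export
conservation_value <- function(query, subject, params = align_params(),
                               query_id = "query",
                               subject_id = "subject") {
  if (!nzchar(query)) stop("zero-length query")
  aln <- local_align(query, subject, params)
  cv <- aln$identical_nt / nchar(query) * 100
  data.frame(query_id = query_id, subject_id = subject_id,
             identical_nt = aln$identical_nt,
             query_length = nchar(query),
             conservation_value = cv,
             retained = cv >= params$retain_threshold,
             score = aln$score, orientation = aln$orientation,
             stringsAsFactors = FALSE)
}

#' Scan a transcript for open reading frames
#'
#' Reports every ORF in the three sense frames: a start codon (ATG, GTG
#' or TTG) followed in frame by a stop codon, with the stop excluded from
#' the codon count. Nested ORFs sharing a stop are each reported. A
#' transcript with no ORF longer than `min_codons` codons is flagged
#' non-coding.
#'
#' @param transcript Sequence over A/C/G/T.
#' @param min_codons Minimum ORF length in codons, exclusive bound
#'   (default 10: ORFs of more than 10 codons count).
#' @return List with `orfs` (data.frame: `frame` 0..2, `start`, `end` --
#'   1-based, stop codon excluded -- and `codons`) and `non_coding`
#'   (logical).
#' @export
orf_scan <- function(transcript, min_codons = 10) {
  stopifnot(min_codons >= 1)
  transcript <- toupper(transcript)
  n <- nchar(transcript)
  starts <- c("ATG", "GTG", "TTG"); stops <- c("TAA", "TAG", "TGA")
  rows <- list()
  for (f in 0:2) {
    if (n - f < 6L) next
    ncod <- (n - f) %/% 3L
    cod <- substring(transcript, f + seq(1L, 3L * ncod - 2L, 3L),
                     f + seq(3L, 3L * ncod, 3L))
    stop_i <- which(cod %in% stops)
    for (si in which(cod %in% starts)) {
      nxt <- stop_i[stop_i > si]
      if (!length(nxt)) next
      len <- nxt[1L] - si
      if (len > min_codons)
        rows[[length(rows) + 1L]] <- data.frame(
          frame = f, start = f + 3L * (si - 1L) + 1L,
          end = f + 3L * (nxt[1L] - 1L), codons = len)
    }
  }
  orfs <- if (length(rows)) do.call(rbind, rows)
    else data.frame(frame = integer(0), start = integer(0),
                    end = integer(0), codons = integer(0))
  list(orfs = orfs[order(orfs$start), , drop = FALSE],
       non_coding = nrow(orfs) == 0L)
}

#' GC content of a sequence, in percent
#'
#' N bases are excluded from both numerator and denominator.
#'
#' @param seq Non-empty sequence.
#' @return Percentage of G+C among non-N bases.
#' @export
gc_content <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  b <- strsplit(toupper(seq), "")[[1L]]
  b <- b[b != "N"]
  if (!length(b)) return(NA_real_)
  sum(b %in% c("G", "C")) / length(b) * 100
}
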