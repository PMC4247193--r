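#' 5'-UTR annotation parameters
#'
#' An mRNA is leaderless when its 5'-UTR is at most `leaderless_max` nt
#' (such transcripts start at or almost at the start codon and are
#' translated without a ribosome binding site); a long 5'-UTR is
#' `long_min`..`long_max` nt. Start-codon re-assignment scans
#' `scan_window` bp downstream of the TSS for alternative in-frame starts
#' and accepts a candidate supported by a ribosome binding site (RBS)
#' whose 3' end lies `rbs_spacer_min`..`rbs_spacer_max` nt upstream of the
#' candidate, or one that moves the transcript out of the leaderless
#' class.
#'
#' @param leaderless_max Maximum leaderless 5'-UTR length (default 8 nt).
#' @param long_min,long_max Long-UTR bounds (default 50 and 300 nt).
#' @param rbs_pattern IUPAC consensus of the RBS (default `GGDGRD`).
#' @param rbs_spacer_min,rbs_spacer_max Allowed spacer between RBS 3' end
#'   and start codon (default 4..15 nt).
#' @param scan_window Alternative-start scan window downstream of the TSS
#'   (default 100 bp).
#' @return Named list of UTR parameters.
#' @export
utr_params <- function(leaderless_max = 8, long_min = 50, long_max = 300,
                       rbs_pattern = "GGDGRD", rbs_spacer_min = 4,
                       rbs_spacer_max = 15, scan_window = 100) {
  stopifnot(leaderless_max >= 0, long_min > leaderless_max,
            long_max > long_min, rbs_spacer_min >= 0,
            rbs_spacer_max >= rbs_spacer_min, scan_window > 0)
  list(leaderless_max = leaderless_max, long_min = long_min,
       long_max = long_max, rbs_pattern = rbs_pattern,
       rbs_spacer_min = rbs_spacer_min, rbs_spacer_max = rbs_spacer_max,
       scan_window = scan_window)
}

#' 5'-UTR length of a TSS relative to a start codon
#'
#' Distance in nt from the TSS to the first base of the start codon; 0
#' when the TSS coincides with it. A TSS downstream of the start codon has
#' no 5'-UTR (it is internal) and is an error.
#'
#' @param pos TSS position (1-based).
#' @param strand `"+"` or `"-"`.
#' @param start_codon_pos First base of the start codon (strand-aware).
#' @return Non-negative integer length in nt.
#' @export
utr_length <- function(pos, strand, start_codon_pos) {
  d <- upstream_distance(pos, strand, start_codon_pos)
  if (any(d < 0))
    stop("TSS downstream of the start codon has no 5'-UTR ",
         "(internal TSS): position ", pos[d < 0][1L])
  as.integer(d)
}

#' Annotate 5'-UTRs for primary and secondary TSS
#'
#' Computes per-mRNA 5'-UTR length, leaderless and long-UTR flags, UTR GC
#' content, and the best RBS match (IUPAC consensus, spacer within the
#' configured bounds) inside the UTR.
#'
#' @param records Classified TSS data.frame with `pTSS`/`sTSS` rows (from
#'   [assign_primary_secondary()]).
#' @param annotation A `genome_annotation`.
#' @param params [utr_params()].
#' @return data.frame with one row per (p/sTSS, gene): `locus_tag`,
#'   `tss_pos`, `strand`, `class`, `utr_length`, `leaderless`, `long_utr`,
#'   `utr_gc`, `rbs_found`, `rbs_spacer`, `rbs_seq`.
#' @export
annotate_utrs <- function(records, annotation, params = utr_params()) {
  ps <- records[records$class %in% c("pTSS", "sTSS"), , drop = FALSE]
  if (nrow(ps) == 0L) stop("no primary/secondary TSS in records")
  ft <- annotation$features
  fidx <- match(ps$locus_tag, ft$locus_tag)
  len <- utr_length(ps$pos, ps$strand, ft$start_codon_pos[fidx])
  utr_seq <- character(nrow(ps))
  for (i in seq_len(nrow(ps))) {
    utr_seq[i] <- if (len[i] == 0L) "" else if (ps$strand[i] == "+")
      subseq_chr(annotation$genome, ps$seqid[i], ps$pos[i],
                 ps$pos[i] + len[i] - 1L)
    else
      subseq_chr(annotation$genome, ps$seqid[i], ps$pos[i] - len[i] + 1L,
                 ps$pos[i], "-")
  }
  rbs <- lapply(seq_len(nrow(ps)), function(i)
    find_rbs(utr_seq[i], params))
  data.frame(locus_tag = ps$locus_tag, tss_pos = ps$pos,
             seqid = ps$seqid, strand = ps$strand, class = ps$class,
             utr_length = len,
             leaderless = len <= params$leaderless_max,
             long_utr = len >= params$long_min & len <= params$long_max,
             utr_gc = vapply(utr_seq, function(s)
               if (nzchar(s)) gc_content(s) else NA_real_, numeric(1)),
             rbs_found = vapply(rbs, function(h) h$found, logical(1)),
             rbs_spacer = vapply(rbs, function(h) h$spacer, integer(1)),
             rbs_seq = vapply(rbs, function(h) h$seq, character(1)),
             stringsAsFactors = FALSE)
}

# best (closest to the start codon) RBS match inside a UTR sequence given
# in transcription direction; the start codon sits right after the UTR
find_rbs <- function(utr_seq, params = utr_params()) {
  w <- nchar(params$rbs_pattern)
  none <- list(found = FALSE, spacer = NA_integer_, seq = NA_character_)
  L <- nchar(utr_seq)
  if (L < w + params$rbs_spacer_min) return(none)
  hits <- match_iupac(utr_seq, params$rbs_pattern)
  if (!length(hits)) return(none)
  spacer <- L - (hits + w - 1L)
  ok <- spacer >= params$rbs_spacer_min & spacer <= params$rbs_spacer_max
  if (!any(ok)) return(none)
  best <- hits[ok][which.min(spacer[ok])]
  list(found = TRUE, spacer = L - (best + w - 1L),
       seq = substr(utr_seq, best, best + w - 1L))
}

#' Summarise a 5'-UTR annotation
#'
#' @param utrs data.frame from [annotate_utrs()].
#' @param params [utr_params()].
#' @return List with `n`, `median_utr`, `leaderless_fraction`,
#'   `long_fraction`, `rbs_fraction` and `long_utr_gc` (mean GC of long
#'   UTRs, `NA` when none).
#' @export
classify_utrs <- function(utrs, params = utr_params()) {
  if (nrow(utrs) == 0L) stop("empty UTR table")
  list(n = nrow(utrs),
       median_utr = median(utrs$utr_length),
       leaderless_fraction = mean(utrs$leaderless),
       long_fraction = mean(utrs$long_utr),
       rbs_fraction = mean(utrs$rbs_found),
       long_utr_gc = if (any(utrs$long_utr))
         mean(utrs$utr_gc[utrs$long_utr]) else NA_real_)
}

# codon walk from the annotated start, in transcription direction
coding_codons <- function(annotation, feature_row, n_codons) {
  ft <- feature_row
  n_codons <- min(n_codons,
                  (ft$end - ft$start + 1L) %/% 3L)
  s <- if (ft$strand == "+")
    subseq_chr(annotation$genome, ft$seqid, ft$start,
               ft$start + 3L * n_codons - 1L)
  else
    subseq_chr(annotation$genome, ft$seqid, ft$end - 3L * n_codons + 1L,
               ft$end, "-")
  substring(s, seq(1L, 3L * n_codons - 2L, by = 3L),
            seq(3L, 3L * n_codons, by = 3L))
}

#' Scan one gene for an alternative downstream start codon
#'
#' Implements the leaderless-mRNA review: alternative in-frame starts
#' (ATG preferred, then GTG, then TTG) strictly downstream of the
#' annotated start and within `scan_window` bp of the TSS are examined
#' before the first in-frame stop; the nearest candidate (within its
#' codon-priority tier) is accepted when it carries an upstream RBS, or
#' when adopting it moves a leaderless transcript out of the leaderless
#' class.
#'
#' @param annotation A `genome_annotation`.
#' @param locus_tag Gene to scan.
#' @param tss_pos TSS position driving the review.
#' @param params [utr_params()].
#' @return One-row data.frame describing the re-assignment, or `NULL` when
#'   no candidate qualifies. Columns: `locus_tag`, `tss_pos`, `old_start`,
#'   `new_start`, `new_codon`, `frame_offset_codons`, `rbs_found`,
#'   `old_utr`, `new_utr`.
#' @export
reassign_start_codon <- function(annotation, locus_tag, tss_pos,
                                 params = utr_params()) {
  ft <- annotation$features
  row <- ft[ft$locus_tag == locus_tag, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown locus_tag: ", locus_tag)
  d_old <- upstream_distance(tss_pos, row$strand, row$start_codon_pos)
  max_codons <- (params$scan_window + abs(d_old)) %/% 3L + 2L
  codons <- coding_codons(annotation, row, max_codons)
  stops <- c("TAA", "TAG", "TGA")
  first_stop <- which(codons %in% stops)
  last_ok <- if (length(first_stop)) first_stop[1L] - 1L
    else length(codons)
  if (last_ok < 2L) return(NULL)
  cand_i <- seq(2L, last_ok)
  # new UTR length if the candidate became the start codon; the candidate
  # must lie in the TSS..TSS+scan_window stretch of the transcript
  new_utr <- d_old + 3L * (cand_i - 1L)
  cand_i <- cand_i[new_utr >= 0 & new_utr <= params$scan_window]
  if (!length(cand_i)) return(NULL)
  leaderless_now <- d_old >= 0 && d_old <= params$leaderless_max
  for (codon in c("ATG", "GTG", "TTG")) {
    for (i in cand_i[codons[cand_i] == codon]) {
      nu <- d_old + 3L * (i - 1L)
      rbs <- rbs_upstream_of(annotation, row, offset_codons = i - 1L,
                             tss_pos = tss_pos, params = params)
      escapes <- leaderless_now && nu > params$leaderless_max
      if (rbs$found || escapes) {
        new_start <- if (row$strand == "+")
          row$start + 3L * (i - 1L) else row$end - 3L * (i - 1L)
        return(data.frame(locus_tag = locus_tag, tss_pos = tss_pos,
                          old_start = row$start_codon_pos,
                          new_start = new_start, new_codon = codon,
                          frame_offset_codons = i - 1L,
                          rbs_found = rbs$found,
                          old_utr = as.integer(d_old),
                          new_utr = as.integer(nu),
                          stringsAsFactors = FALSE))
      }
    }
  }
  NULL
}

# RBS search upstream of a candidate start codon offset_codons codons
# downstream of the annotated start; the matched hexamer must lie inside
# the transcript (at or downstream of the TSS)
rbs_upstream_of <- function(annotation, row, offset_codons, tss_pos,
                            params) {
  w <- nchar(params$rbs_pattern)
  span <- params$rbs_spacer_max + w
  if (row$strand == "+") {
    cand <- row$start + 3L * offset_codons
    lo <- max(1L, cand - span, tss_pos)
    if (cand - lo < params$rbs_spacer_min + w)
      return(list(found = FALSE, spacer = NA_integer_,
                  seq = NA_character_))
    s <- subseq_chr(annotation$genome, row$seqid, lo, cand - 1L)
  } else {
    cand <- row$end - 3L * offset_codons
    hi <- min(length(annotation$genome[[row$seqid]]),
              cand + span, tss_pos)
    if (hi - cand < params$rbs_spacer_min + w)
      return(list(found = FALSE, spacer = NA_integer_,
                  seq = NA_character_))
    s <- subseq_chr(annotation$genome, row$seqid, cand + 1L, hi, "-")
  }
  find_rbs(s, params)
}

#' Review leaderless and start-proximal internal TSS for start
#' re-assignment
#'
#' Applies [reassign_start_codon()] to every leaderless primary/secondary
#' TSS and to every internal TSS lying within `scan_window` bp downstream
#' of its gene's annotated start. At most one re-assignment is made per
#' gene.
#'
#' @param records Classified TSS data.frame (pTSS/sTSS rows need
#'   `distance`).
#' @param annotation A `genome_annotation`.
#' @param params [utr_params()].
#' @return data.frame of re-assignments (possibly 0 rows).
#' @export
reassign_start_codons <- function(records, annotation,
                                  params = utr_params()) {
  ft <- annotation$features
  lead <- records$class %in% c("pTSS", "sTSS") &
    records$distance <= params$leaderless_max
  d_all <- upstream_distance(records$pos, records$strand,
                             ft$start_codon_pos[match(records$locus_tag,
                                                      ft$locus_tag)])
  itss <- records$class == "iTSS" & !is.na(d_all) &
    d_all < 0 & -d_all <= params$scan_window
  cand <- records[which(lead | itss), , drop = FALSE]
  out <- list(); done <- character(0)
  for (i in seq_len(nrow(cand))) {
    if (cand$locus_tag[i] %in% done) next
    r <- reassign_start_codon(annotation, cand$locus_tag[i],
                              cand$pos[i], params)
    if (!is.null(r)) {
      out[[length(out) + 1L]] <- r
      done <- c(done, cand$locus_tag[i])
    }
  }
  if (!length(out))
    return(data.frame(locus_tag = character(0), tss_pos = integer(0),
                      old_start = integer(0), new_start = integer(0),
                      new_codon = character(0),
                      frame_offset_codons = integer(0),
                      rbs_found = logical(0), old_utr = integer(0),
                      new_utr = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Apply start-codon re-assignments and re-categorise TSS
#'
#' Moves each re-assigned gene's start codon, recomputes TSS classes and
#' 5'-UTRs against the updated annotation, and reports the change log.
#' With an empty re-assignment set the records are returned unchanged.
#'
#' @param tss Unified TSS data.frame (as from [detect_tss()]).
#' @param reassignments data.frame from [reassign_start_codons()].
#' @param annotation A `genome_annotation`.
#' @param cls_params [classification_params()].
#' @param params [utr_params()].
#' @return List with `annotation` (updated), `records` (re-classified),
#'   `utrs` (recomputed) and `changes` (the re-assignment table).
#' @export
recategorize <- function(tss, reassignments, annotation,
                         cls_params = classification_params(),
                         params = utr_params()) {
  ft <- annotation$features
  for (i in seq_len(nrow(reassignments))) {
    j <- which(ft$locus_tag == reassignments$locus_tag[i])
    if (ft$strand[j] == "+") ft$start[j] <- reassignments$new_start[i]
    else ft$end[j] <- reassignments$new_start[i]
  }
  ann2 <- genome_annotation(annotation$genome,
                            ft[, setdiff(names(ft), "start_codon_pos")],
                            annotation$operons)
  records <- assign_primary_secondary(
    classify_tss(tss, ann2, cls_params))
  list(annotation = ann2, records = records,
       utrs = annotate_utrs(records, ann2, params),
       changes = reassignments)
}
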