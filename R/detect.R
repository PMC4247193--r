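#' TSS detection parameters
#'
#' The detector requires, at a candidate position in a treated library,
#' (i) a minimum number of raw 5'-end reads (`min_height`, the evidence
#' floor), (ii) a minimum fold step over the position immediately upstream
#' in the direction of transcription (`min_step_factor`, separates sharp
#' 5' ends from sloping coverage), and (iii) a minimum TEX enrichment of
#' the treated over the untreated library (`min_enrichment`, separates
#' primary 5' ends from processing sites). Step and enrichment factors are
#' computed on library-size-normalised heights (reads per million) so that
#' treated and untreated libraries of different depths are comparable;
#' `pseudocount` (in normalised units) stabilises both ratios.
#'
#' @param min_height Minimum raw 5'-end read count at the position
#'   (default 5 reads).
#' @param min_step_factor Minimum fold increase over the upstream
#'   neighbour (default 2).
#' @param min_enrichment Minimum treated/untreated height ratio
#'   (default 2).
#' @param cluster_window Candidates within this many nt on one strand are
#'   merged (default 3).
#' @param pseudocount Added to the denominator of both ratios, in
#'   normalised units (default 1).
#' @param per_million Report heights as reads per million (default `TRUE`).
#' @return Named list of detection parameters.
#' @export
detection_params <- function(min_height = 5, min_step_factor = 2,
                             min_enrichment = 2, cluster_window = 3,
                             pseudocount = 1, per_million = TRUE) {
  stopifnot(min_height > 0, min_step_factor > 0, min_enrichment > 0,
            cluster_window >= 1, pseudocount > 0)
  list(min_height = min_height, min_step_factor = min_step_factor,
       min_enrichment = min_enrichment, cluster_window = cluster_window,
       pseudocount = pseudocount, per_million = isTRUE(per_million))
}

#' Step and enrichment statistics at one position
#'
#' @param treated,untreated `coverage_track` objects sharing the replicon
#'   layout.
#' @param seqid Replicon name.
#' @param pos 1-based position.
#' @param strand `"+"` or `"-"`; on the minus strand "upstream" is
#'   `pos + 1`.
#' @param params [detection_params()].
#' @return Named numeric vector: `height` (normalised treated height),
#'   `raw` (raw treated count), `step_factor`, `enrichment_factor`.
#' @export
step_metrics <- function(treated, untreated, seqid, pos, strand,
                         params = detection_params()) {
  tn <- normalize_track(treated, params$per_million)[[seqid]]
  un <- normalize_track(untreated, params$per_million)[[seqid]]
  sv <- if (strand == "+") "fwd" else "rev"
  n <- length(tn[[sv]])
  if (pos < 1L || pos > n) stop("position outside replicon ", seqid)
  up <- if (strand == "+") pos - 1L else pos + 1L
  hup <- if (up < 1L || up > n) 0 else tn[[sv]][up]
  h <- tn[[sv]][pos]
  c(height = h,
    raw = treated$counts[[seqid]][[sv]][pos],
    step_factor = h / max(hup, params$pseudocount),
    enrichment_factor = h / (un[[sv]][pos] + params$pseudocount))
}

#' Call TSS candidates from one treated/untreated library pair
#'
#' Scans both strands of every replicon and reports each position passing
#' the three thresholds of [detection_params()].
#'
#' @inheritParams step_metrics
#' @return data.frame with columns `seqid`, `pos`, `strand`, `height`
#'   (normalised treated height), `raw`, `step_factor`,
#'   `enrichment_factor`, `library_id`.
#' @export
call_candidates <- function(treated, untreated,
                            params = detection_params()) {
  if (!identical(lapply(treated$counts, function(cc) length(cc$fwd)),
                 lapply(untreated$counts, function(cc) length(cc$fwd))))
    stop("treated and untreated tracks have different replicon layouts")
  tn <- normalize_track(treated, params$per_million)
  un <- normalize_track(untreated, params$per_million)
  out <- list()
  for (rep in names(treated$counts)) {
    for (sv in c("fwd", "rev")) {
      strand <- if (sv == "fwd") "+" else "-"
      h <- tn[[rep]][[sv]]
      raw <- treated$counts[[rep]][[sv]]
      n <- length(h)
      if (n == 0L) next
      hup <- if (strand == "+") c(0, h[-n]) else c(h[-1L], 0)
      step <- h / pmax(hup, params$pseudocount)
      enr <- h / (un[[rep]][[sv]] + params$pseudocount)
      sel <- which(raw >= params$min_height &
                   step >= params$min_step_factor &
                   enr >= params$min_enrichment)
      if (length(sel))
        out[[length(out) + 1L]] <- data.frame(
          seqid = rep, pos = sel, strand = strand,
          height = h[sel], raw = raw[sel],
          step_factor = step[sel], enrichment_factor = enr[sel],
          library_id = treated$library_id,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(seqid = character(0), pos = integer(0),
                      strand = character(0), height = numeric(0),
                      raw = numeric(0), step_factor = numeric(0),
                      enrichment_factor = numeric(0),
                      library_id = character(0),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df[order(df$seqid, df$pos, df$strand), , drop = FALSE]
}

# single-linkage groups of sorted positions with gaps <= window
chain_groups <- function(pos, window) {
  if (length(pos) == 0L) return(integer(0))
  cumsum(c(1L, as.integer(diff(pos) > window)))
}

#' Merge near-duplicate candidates on one strand
#'
#' Single-linkage clustering: candidates on the same strand whose positions
#' are within `cluster_window` nt of the next candidate belong to one
#' cluster. The representative is the position of maximum height; ties go
#' to the most upstream position in the direction of transcription. The
#' representative keeps its own height (heights are not summed).
#'
#' @param candidates data.frame as from [call_candidates()].
#' @param cluster_window Maximum gap in nt (default 3).
#' @return data.frame of cluster representatives.
#' @export
cluster_candidates <- function(candidates, cluster_window = 3) {
  if (nrow(candidates) == 0L) return(candidates)
  parts <- split(candidates,
                 paste(candidates$seqid, candidates$strand))
  reps <- lapply(parts, function(df) {
    df <- df[order(df$pos), , drop = FALSE]
    grp <- chain_groups(df$pos, cluster_window)
    picked <- vapply(split(seq_len(nrow(df)), grp), function(idx) {
      h <- df$height[idx]
      best <- idx[h == max(h)]
      if (df$strand[1L] == "+") best[which.min(df$pos[best])]
      else best[which.max(df$pos[best])]
    }, integer(1))
    df[picked, , drop = FALSE]
  })
  df <- do.call(rbind, reps)
  rownames(df) <- NULL
  df[order(df$seqid, df$pos, df$strand), , drop = FALSE]
}

#' Unify candidate lists across libraries
#'
#' Union semantics: a TSS found in any library is reported. Candidates
#' within `tolerance` nt on the same strand are unified to the position
#' with the highest height summed over libraries; `detected_in` records
#' the contributing libraries and `height_<lib>` the per-library
#' normalised heights.
#'
#' @param candidate_lists List of data.frames from [cluster_candidates()].
#' @param tolerance Maximum position difference in nt (default 1).
#' @return data.frame with one row per unified TSS: `seqid`, `pos`,
#'   `strand`, `height` (sum over libraries), `enrichment_factor` (max),
#'   `n_libraries`, `detected_in`, and one `height_<lib>` column per
#'   library.
#' @export
merge_libraries <- function(candidate_lists, tolerance = 1) {
  stopifnot(length(candidate_lists) >= 1L)
  all <- do.call(rbind, candidate_lists)
  libs <- unique(all$library_id)
  if (nrow(all) == 0L) {
    out <- data.frame(seqid = character(0), pos = integer(0),
                      strand = character(0), height = numeric(0),
                      enrichment_factor = numeric(0),
                      n_libraries = integer(0),
                      detected_in = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  parts <- split(all, paste(all$seqid, all$strand))
  rows <- lapply(parts, function(df) {
    df <- df[order(df$pos), , drop = FALSE]
    grp <- chain_groups(df$pos, tolerance)
    do.call(rbind, lapply(split(df, grp), function(g) {
      bypos <- tapply(g$height, g$pos, sum)
      best <- as.integer(names(bypos)[which.max(bypos)])
      perlib <- tapply(g$height, g$library_id, max)
      hl <- setNames(rep(0, length(libs)), libs)
      hl[names(perlib)] <- perlib
      out <- data.frame(seqid = g$seqid[1L], pos = best,
                        strand = g$strand[1L],
                        height = sum(perlib),
                        enrichment_factor = max(g$enrichment_factor),
                        n_libraries = length(perlib),
                        detected_in = paste(sort(names(perlib)),
                                            collapse = ","),
                        stringsAsFactors = FALSE)
      for (lib in libs) out[[paste0("height_", lib)]] <- hl[[lib]]
      out
    }))
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df[order(df$seqid, df$pos, df$strand), , drop = FALSE]
}

#' Detect TSS across several treated/untreated library pairs
#'
#' Runs [call_candidates()] and [cluster_candidates()] per condition and
#' unifies the per-condition calls with [merge_libraries()].
#'
#' @param treated_tracks,untreated_tracks Named lists of `coverage_track`
#'   objects; names are conditions and must match pairwise.
#' @param params [detection_params()].
#' @param tolerance Cross-library position tolerance in nt (default 1).
#' @return Unified TSS data.frame (see [merge_libraries()]).
#' @export
detect_tss <- function(treated_tracks, untreated_tracks,
                       params = detection_params(), tolerance = 1) {
  conds <- names(treated_tracks)
  stopifnot(!is.null(conds), all(conds %in% names(untreated_tracks)))
  per_cond <- lapply(conds, function(cond)
    cluster_candidates(
      call_candidates(treated_tracks[[cond]],
                      untreated_tracks[[cond]], params),
      params$cluster_window))
  merge_libraries(per_cond, tolerance)
}
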