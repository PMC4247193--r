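#' Construct a 5'-end coverage track
#'
#' Per-strand integer counts of read 5' ends at every genome position for
#' one sequencing library. `library_size` is the total number of mapped
#' 5' ends on both strands.
#'
#' @param counts Named list, one entry per replicon, each a list with
#'   integer vectors `fwd` and `rev` of the replicon length.
#' @param library_id Library identifier.
#' @param condition Growth condition the library came from.
#' @param treated `TRUE` for a TEX-treated library, `FALSE` for untreated.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(counts, library_id, condition, treated) {
  for (rep in names(counts)) {
    cc <- counts[[rep]]
    stopifnot(is.list(cc), all(c("fwd", "rev") %in% names(cc)))
    if (length(cc$fwd) != length(cc$rev))
      stop("fwd/rev length mismatch on replicon ", rep)
    if (any(cc$fwd < 0) || any(cc$rev < 0))
      stop("negative count on replicon ", rep)
  }
  structure(list(counts = counts,
                 library_id = library_id,
                 condition = condition,
                 treated = isTRUE(treated),
                 library_size = sum(vapply(counts, function(cc)
                   sum(cc$fwd) + sum(cc$rev), numeric(1)))),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track", x$library_id, "(", x$condition,
      if (x$treated) "TEX+" else "TEX-", "):",
      length(x$counts), "replicon(s),", x$library_size, "5' ends\n")
  invisible(x)
}

import_wig_strand <- function(path, rlen) {
  out0 <- lapply(rlen, function(n) integer(n))
  # a declaration-only file (no data rows) is a legal all-zero track but
  # trips rtracklayer's section parser, so short-circuit it
  lines <- readLines(path)
  if (!any(grepl("^\\s*[0-9]", lines))) return(out0)
  gr <- rtracklayer::import(path, format = "wig")
  out <- lapply(rlen, function(n) integer(n))
  if (length(gr) == 0L) return(out)
  if (any(GenomicRanges::width(gr) != 1L))
    stop("wiggle spans wider than 1 nt in ", path,
         " (5'-end tracks are single-position)")
  sq <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(sq), names(rlen))
  if (length(unknown))
    stop("wiggle chrom not in genome: ", unknown[1L], " in ", path)
  pos <- GenomicRanges::start(gr)
  if (any(pos > rlen[sq]))
    stop("wiggle position beyond replicon end in ", path)
  val <- gr$score
  if (any(val < 0)) stop("negative value in wiggle ", path)
  key <- paste(sq, pos)
  if (anyDuplicated(key))
    stop("duplicate position in wiggle ", path, ": ",
         key[duplicated(key)][1L])
  for (rep in unique(sq)) {
    sel <- sq == rep
    out[[rep]][pos[sel]] <- as.integer(round(val[sel]))
  }
  out
}

#' Read a per-strand wiggle pair into a coverage track
#'
#' Input files are variableStep wiggle with 1-based positions, one file per
#' strand. Positions absent from the file are zero; duplicate positions and
#' positions beyond the replicon end are errors.
#'
#' @param fwd_path,rev_path Wiggle files for the forward and reverse strand.
#' @param genome A [Biostrings::DNAStringSet].
#' @inheritParams coverage_track
#' @return A `coverage_track`.
#' @export
read_coverage <- function(fwd_path, rev_path, genome, library_id,
                          condition = library_id, treated = TRUE) {
  rlen <- setNames(Biostrings::width(genome), names(genome))
  fwd <- import_wig_strand(fwd_path, rlen)
  rev <- import_wig_strand(rev_path, rlen)
  counts <- lapply(names(rlen), function(rep)
    list(fwd = fwd[[rep]], rev = rev[[rep]]))
  names(counts) <- names(rlen)
  coverage_track(counts, library_id, condition, treated)
}

write_wig_strand <- function(vecs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rep in names(vecs)) {
    v <- vecs[[rep]]
    nz <- which(v != 0)
    if (length(nz)) {
      writeLines(paste0("variableStep chrom=", rep), con)
      writeLines(paste(nz, v[nz]), con)
    }
  }
  invisible(path)
}

#' Write a coverage track as a per-strand wiggle pair
#'
#' Emits variableStep wiggle (1-based positions, zero positions omitted),
#' the on-disk dialect [read_coverage()] consumes.
#'
#' @param track A `coverage_track`.
#' @param fwd_path,rev_path Output paths for the two strands.
#' @return `c(fwd_path, rev_path)`, invisibly.
#' @export
write_coverage <- function(track, fwd_path, rev_path) {
  write_wig_strand(lapply(track$counts, `[[`, "fwd"), fwd_path)
  write_wig_strand(lapply(track$counts, `[[`, "rev"), rev_path)
  invisible(c(fwd_path, rev_path))
}

#' Library-size normalised 5'-end heights
#'
#' Scales counts to reads per million mapped 5' ends:
#' `height(p) = counts(p) * 1e6 / library_size`. With `per_million = FALSE`
#' heights equal the raw counts.
#'
#' @param track A `coverage_track`.
#' @param per_million Normalise to reads per million (default `TRUE`).
#' @return Named list per replicon with numeric vectors `fwd` and `rev`.
#' @export
normalize_track <- function(track, per_million = TRUE) {
  if (!per_million)
    return(lapply(track$counts, function(cc)
      list(fwd = as.numeric(cc$fwd), rev = as.numeric(cc$rev))))
  if (track$library_size <= 0)
    stop("cannot normalize track with zero library size: ",
         track$library_id)
  f <- 1e6 / track$library_size
  lapply(track$counts, function(cc)
    list(fwd = cc$fwd * f, rev = cc$rev * f))
}
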