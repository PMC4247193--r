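#' Run the TSS annotation pipeline end to end
#'
#' Detection across all treated/untreated pairs, classification,
#' primary/secondary assignment, 5'-UTR annotation, start-codon
#' re-assignment and re-categorisation, and the category summary.
#'
#' @param annotation A `genome_annotation`.
#' @param treated_tracks,untreated_tracks Named lists of
#'   `coverage_track`s keyed by condition.
#' @param config Configuration as from [default_config()].
#' @return List with `tss` (unified candidates), `records` (classified,
#'   after re-categorisation), `utrs`, `reassignments`, `summary` and
#'   `annotation` (post re-assignment).
#' @export
run_tss_pipeline <- function(annotation, treated_tracks,
                             untreated_tracks,
                             config = default_config()) {
  tss <- detect_tss(treated_tracks, untreated_tracks,
                    config$detection)
  records <- assign_primary_secondary(
    classify_tss(tss, annotation, config$classification))
  reass <- reassign_start_codons(records, annotation, config$utr)
  if (nrow(reass)) {
    rec <- recategorize(tss, reass, annotation, config$classification,
                        config$utr)
    records <- rec$records
    utrs <- rec$utrs
    annotation <- rec$annotation
  } else {
    utrs <- annotate_utrs(records, annotation, config$utr)
  }
  list(tss = tss, records = records, utrs = utrs,
       reassignments = reass,
       summary = category_summary(records),
       annotation = annotation)
}

#' Reflect an annotation to the opposite strand
#'
#' Reverse-complements every replicon and mirrors all feature
#' coordinates, swapping strands. Running the pipeline on mirrored
#' inputs must give outputs identical under [mirror_positions()]; this
#' is the strand-mirror invariance used in validation.
#'
#' @param annotation A `genome_annotation`.
#' @return The mirrored `genome_annotation`.
#' @export
mirror_annotation <- function(annotation) {
  genome <- Biostrings::reverseComplement(annotation$genome)
  names(genome) <- names(annotation$genome)
  rlen <- setNames(Biostrings::width(genome), names(genome))
  ft <- annotation$features
  L <- rlen[ft$seqid]
  new_start <- L - ft$end + 1L
  new_end <- L - ft$start + 1L
  ft$start <- as.integer(new_start)
  ft$end <- as.integer(new_end)
  ft$strand <- ifelse(ft$strand == "+", "-", "+")
  genome_annotation(genome,
                    ft[, setdiff(names(ft), "start_codon_pos")],
                    annotation$operons)
}

#' Reflect a coverage track to the opposite strand
#'
#' @param track A `coverage_track`.
#' @return The mirrored `coverage_track` (positions reversed, strands
#'   swapped).
#' @export
mirror_track <- function(track) {
  counts <- lapply(track$counts, function(cc)
    list(fwd = base::rev(cc$rev), rev = base::rev(cc$fwd)))
  coverage_track(counts, track$library_id, track$condition,
                 track$treated)
}

#' Mirror genome positions
#'
#' @param pos Positions (1-based).
#' @param replicon_length Length of the replicon.
#' @return `replicon_length - pos + 1`.
#' @export
mirror_positions <- function(pos, replicon_length) {
  as.integer(replicon_length - pos + 1L)
}
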