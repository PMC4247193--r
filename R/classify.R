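#' TSS classification parameters
#'
#' Positional definitions of the five TSS classes relative to annotated
#' genes: a TSS 0..`max_upstream` bp upstream of a start codon on the
#' sense strand is primary or secondary for that gene (pTSS if it has the
#' most reads, otherwise sTSS); a TSS inside a gene on the sense strand is
#' internal (iTSS); a TSS inside, or within `antisense_flank` bp of, a gene
#' on the antisense strand is antisense (aTSS); a TSS matching none of
#' these is orphan (oTSS). `terminus_window` sizes the windows around
#' translation start and stop codons used to summarise the positional bias
#' of antisense transcription.
#'
#' @param max_upstream Maximum TSS-to-start-codon distance for p/sTSS
#'   (default 300 bp, inclusive).
#' @param antisense_flank Flank around a gene within which an
#'   opposite-strand TSS is antisense (default 100 bp, inclusive).
#' @param terminus_window Window around start/stop codons for the
#'   antisense terminus summary (default 150 bp).
#' @return Named list of classification parameters.
#' @export
classification_params <- function(max_upstream = 300,
                                  antisense_flank = 100,
                                  terminus_window = 150) {
  stopifnot(max_upstream > 0, antisense_flank > 0, terminus_window > 0)
  list(max_upstream = max_upstream, antisense_flank = antisense_flank,
       terminus_window = terminus_window)
}

# strand-aware signed distance from TSS to the first base of the start
# codon; positive = TSS upstream of the start codon
upstream_distance <- function(pos, strand, start_codon_pos) {
  ifelse(strand == "+", start_codon_pos - pos, pos - start_codon_pos)
}

#' Classify TSS against a gene annotation
#'
#' Assigns every TSS all classes its geometry supports (multi-class
#' membership is expected: an iTSS can simultaneously be the pTSS of a
#' downstream gene). Upstream sense assignments are provisional
#' (`upstream`) until [assign_primary_secondary()] splits them into pTSS
#' and sTSS by read support. A TSS exactly at the first base of a start
#' codon counts as upstream with a 5'-UTR of 0 nt; internal means strictly
#' downstream of the start codon within the gene.
#'
#' @param tss data.frame with columns `seqid`, `pos`, `strand` (and
#'   typically `height` from [detect_tss()]).
#' @param annotation A `genome_annotation`.
#' @param params [classification_params()].
#' @return data.frame with one row per (TSS, assignment): the TSS columns
#'   plus `class` (`upstream`, `iTSS`, `aTSS` or `oTSS`), `locus_tag`
#'   (`NA` for oTSS) and `distance` (TSS to start codon, upstream
#'   assignments only).
#' @export
classify_tss <- function(tss, annotation,
                         params = classification_params()) {
  ft <- annotation$features
  if (nrow(tss) == 0L)
    return(cbind(tss[0, , drop = FALSE],
                 data.frame(class = character(0),
                            locus_tag = character(0),
                            distance = numeric(0))))
  tss_gr <- GenomicRanges::GRanges(tss$seqid,
                                   IRanges::IRanges(tss$pos, width = 1L),
                                   strand = tss$strand)
  gene_gr <- GenomicRanges::GRanges(ft$seqid,
                                    IRanges::IRanges(ft$start, ft$end),
                                    strand = ft$strand)
  # upstream window: max_upstream bp 5' of the start codon, including the
  # start-codon base itself (UTR 0)
  up_start <- ifelse(ft$strand == "+",
                     pmax(1L, ft$start_codon_pos - params$max_upstream),
                     ft$start_codon_pos)
  up_end <- ifelse(ft$strand == "+", ft$start_codon_pos,
                   ft$start_codon_pos + params$max_upstream)
  up_gr <- GenomicRanges::GRanges(ft$seqid,
                                  IRanges::IRanges(up_start, up_end),
                                  strand = ft$strand)
  hit_up <- GenomicRanges::findOverlaps(tss_gr, up_gr)
  # internal: inside the gene, same strand, strictly past the start codon
  hit_in <- GenomicRanges::findOverlaps(tss_gr, gene_gr)
  qi <- S4Vectors::queryHits(hit_in); si <- S4Vectors::subjectHits(hit_in)
  keep_in <- upstream_distance(tss$pos[qi], tss$strand[qi],
                               ft$start_codon_pos[si]) < 0
  # antisense: gene +/- flank, opposite strand
  anti_gr <- GenomicRanges::GRanges(
    ft$seqid,
    IRanges::IRanges(pmax(1L, ft$start - params$antisense_flank),
                     ft$end + params$antisense_flank),
    strand = ifelse(ft$strand == "+", "-", "+"))
  hit_anti <- GenomicRanges::findOverlaps(tss_gr, anti_gr)

  mk <- function(q, s, class) {
    if (!length(q)) return(NULL)
    out <- tss[q, , drop = FALSE]
    out$class <- class
    out$locus_tag <- ft$locus_tag[s]
    out$distance <- ifelse(rep(class == "upstream", length(q)),
                           upstream_distance(tss$pos[q], tss$strand[q],
                                             ft$start_codon_pos[s]),
                           NA_real_)
    out
  }
  res <- rbind(
    mk(S4Vectors::queryHits(hit_up), S4Vectors::subjectHits(hit_up),
       "upstream"),
    mk(qi[keep_in], si[keep_in], "iTSS"),
    mk(S4Vectors::queryHits(hit_anti), S4Vectors::subjectHits(hit_anti),
       "aTSS"))
  assigned <- if (is.null(res)) integer(0)
    else which(paste(tss$seqid, tss$pos, tss$strand) %in%
               paste(res$seqid, res$pos, res$strand))
  orphan_idx <- setdiff(seq_len(nrow(tss)), assigned)
  if (length(orphan_idx)) {
    orp <- tss[orphan_idx, , drop = FALSE]
    orp$class <- "oTSS"
    orp$locus_tag <- NA_character_
    orp$distance <- NA_real_
    res <- rbind(res, orp)
  }
  rownames(res) <- NULL
  res[order(res$seqid, res$pos, res$strand, res$class,
            res$locus_tag), , drop = FALSE]
}

#' Split upstream assignments into primary and secondary TSS
#'
#' For each gene with at least one upstream-sense TSS, the TSS with the
#' highest read support (`height`, the normalised 5'-end height summed
#' over treated libraries) is the primary TSS; all others are secondary.
#' Ties are broken towards the most upstream position in the direction of
#' transcription, for determinism.
#'
#' @param assignments data.frame from [classify_tss()].
#' @return The same data.frame with `upstream` rows relabelled `pTSS` or
#'   `sTSS`.
#' @export
assign_primary_secondary <- function(assignments) {
  up <- assignments$class == "upstream"
  if (!any(up)) return(assignments)
  if (is.null(assignments$height))
    stop("assignments need a 'height' column to rank pTSS")
  idx <- which(up)
  for (g in split(idx, assignments$locus_tag[idx])) {
    h <- assignments$height[g]
    best <- g[h == max(h)]
    if (length(best) > 1L) {
      d <- assignments$distance[best]
      best <- best[which.max(d)]  # most upstream = largest distance
    } else best <- best[1L]
    assignments$class[g] <- "sTSS"
    assignments$class[best] <- "pTSS"
  }
  assignments
}

#' Per-class counts and overlap of a classified TSS set
#'
#' @param records data.frame from [assign_primary_secondary()].
#' @return List with `n_tss` (unique TSS), `n_assignments`, `class_counts`
#'   (named vector over pTSS/sTSS/iTSS/aTSS/oTSS) and `overlap` (square
#'   matrix of TSS shared between class pairs).
#' @export
category_summary <- function(records) {
  classes <- c("pTSS", "sTSS", "iTSS", "aTSS", "oTSS")
  key <- paste(records$seqid, records$pos, records$strand)
  counts <- setNames(vapply(classes, function(cl)
    length(unique(key[records$class == cl])), integer(1)), classes)
  overlap <- matrix(0L, 5, 5, dimnames = list(classes, classes))
  for (a in classes) for (b in classes)
    overlap[a, b] <- length(intersect(unique(key[records$class == a]),
                                      unique(key[records$class == b])))
  list(n_tss = length(unique(key)),
       n_assignments = nrow(records),
       class_counts = counts,
       overlap = overlap)
}

#' Positional bias of antisense TSS around gene termini
#'
#' Fraction of antisense TSS lying within `terminus_window` bp of the
#' translation start codon (5' terminus) or stop codon (3' terminus) of
#' any gene on the opposite strand. A TSS near both termini of a short
#' gene counts in both per-terminus tallies but once overall.
#'
#' @param records Classified data.frame; only `aTSS` rows are used.
#' @param annotation A `genome_annotation`.
#' @param terminus_window Window half-width in bp (default 150).
#' @return List with counts `n_atss`, `n_5prime`, `n_3prime`, `n_neither`
#'   and fractions `frac_terminus`, `frac_5prime`, `frac_3prime`.
#' @export
terminus_enrichment <- function(records, annotation,
                                terminus_window = 150) {
  a <- records[records$class == "aTSS", , drop = FALSE]
  a <- a[!duplicated(paste(a$seqid, a$pos, a$strand)), , drop = FALSE]
  if (nrow(a) == 0L) stop("no antisense TSS in records")
  ft <- annotation$features
  near_term <- function(term_pos) {
    gr <- GenomicRanges::GRanges(
      ft$seqid,
      IRanges::IRanges(pmax(1L, term_pos - terminus_window),
                       term_pos + terminus_window),
      strand = ifelse(ft$strand == "+", "-", "+"))
    q <- GenomicRanges::GRanges(a$seqid,
                                IRanges::IRanges(a$pos, width = 1L),
                                strand = a$strand)
    S4Vectors::countQueryHits(GenomicRanges::findOverlaps(q, gr)) > 0
  }
  start_term <- ft$start_codon_pos
  stop_term <- ifelse(ft$strand == "+", ft$end, ft$start)
  n5 <- near_term(start_term)
  n3 <- near_term(stop_term)
  list(n_atss = nrow(a),
       n_5prime = sum(n5), n_3prime = sum(n3),
       n_neither = sum(!n5 & !n3),
       frac_terminus = mean(n5 | n3),
       frac_5prime = mean(n5), frac_3prime = mean(n3))
}

#' Write a classified TSS table
#'
#' One row per (TSS, class assignment), the master-table shape: multiple
#' class memberships of one TSS give multiple rows. Stable ordering by
#' replicon, position, class.
#'
#' @param records Classified data.frame (from [assign_primary_secondary()],
#'   optionally with UTR columns merged in).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_tss_table <- function(records, path) {
  cols <- c("seqid", "pos", "strand", "class", "locus_tag", "distance",
            "height", "enrichment_factor", "detected_in",
            grep("^height_", names(records), value = TRUE),
            intersect("utr_length", names(records)))
  cols <- intersect(cols, names(records))
  df <- records[, cols, drop = FALSE]
  df <- df[order(df$seqid, df$pos, df$strand, df$class), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a classified TSS table written by [write_tss_table()]
#'
#' @param path Path to the TSV.
#' @return data.frame with one row per (TSS, assignment).
#' @export
read_tss_table <- function(path) {
  read.delim(path, header = TRUE, stringsAsFactors = FALSE)
}
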