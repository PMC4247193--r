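#' Expression analysis parameters
#'
#' @param detection_threshold Normalised reads per transcription unit
#'   below which a TU counts as showing little or no transcription
#'   (default 150; the synthetic background and body-read rates put
#'   silent and active TUs well apart at this value).
#' @param pseudocount Added to both sides of a fold-change contrast
#'   (default 1 normalised unit).
#' @param bin_factors Upper bin edges as multiples of
#'   `detection_threshold` for [expression_bins()] (default 1, 10, 100,
#'   1000; a final open bin catches the rest).
#' @return Named list of expression parameters.
#' @export
expression_params <- function(detection_threshold = 150,
                              pseudocount = 1,
                              bin_factors = c(1, 10, 100, 1000)) {
  stopifnot(detection_threshold > 0, pseudocount >= 0,
            all(diff(bin_factors) > 0))
  list(detection_threshold = detection_threshold,
       pseudocount = pseudocount, bin_factors = bin_factors)
}

#' Per-gene 5'-end read density of one library
#'
#' Sum of strand-matched 5'-end counts within each gene interval divided
#' by the gene length in kb ("average reads per gene"). Positions shared
#' by overlapping same-strand genes count towards every overlapping gene.
#'
#' @param track A `coverage_track`.
#' @param annotation A `genome_annotation`.
#' @return Named numeric vector of reads per kb, one entry per feature.
#' @export
gene_counts <- function(track, annotation) {
  ft <- annotation$features
  if (!all(ft$seqid %in% names(track$counts)))
    stop("track lacks replicons present in the annotation")
  out <- numeric(nrow(ft))
  for (rep in unique(ft$seqid)) {
    cs <- list(`+` = cumsum(as.numeric(track$counts[[rep]]$fwd)),
               `-` = cumsum(as.numeric(track$counts[[rep]]$rev)))
    idx <- which(ft$seqid == rep)
    for (i in idx) {
      cc <- cs[[ft$strand[i]]]
      tot <- cc[ft$end[i]] - if (ft$start[i] > 1L)
        cc[ft$start[i] - 1L] else 0
      out[i] <- tot / ((ft$end[i] - ft$start[i] + 1L) / 1000)
    }
  }
  setNames(out, ft$locus_tag)
}

#' Build a gene-by-library count matrix
#'
#' With `per_million = TRUE` each column is scaled to a common library
#' depth of 10^6 mapped 5' ends. This total-count scaling matches the
#' coverage normalisation upstream and stays unbiased when most of a
#' library's transcription units are silent (stationary phase), a regime
#' in which the median-of-ratios factors of [size_factors()] suffer
#' composition bias.
#'
#' @param tracks Named list of `coverage_track` objects (names become
#'   column names).
#' @param annotation A `genome_annotation`.
#' @param per_million Scale columns to reads per million (default
#'   `FALSE`: raw reads per kb).
#' @return Numeric matrix, genes in rows, libraries in columns.
#' @export
expression_matrix <- function(tracks, annotation, per_million = FALSE) {
  m <- vapply(tracks, gene_counts, annotation = annotation,
              numeric(nrow(annotation$features)))
  rownames(m) <- annotation$features$locus_tag
  if (per_million) {
    sizes <- vapply(tracks, `[[`, numeric(1), "library_size")
    m <- sweep(m, 2L, sizes / 1e6, "/")
  }
  m
}

#' Median-of-ratios library size factors
#'
#' The normalisation underlying count-based RNA-seq comparisons: the size
#' factor of library j is the median over genes of the ratio of that
#' library's count to the gene's geometric mean across libraries. Genes
#' with a zero in any library are excluded from the median. Normalised
#' counts are `count / factor`.
#'
#' @param mat Gene-by-library matrix of non-negative counts.
#' @return Numeric vector of size factors, one per column.
#' @export
size_factors <- function(mat) {
  stopifnot(ncol(mat) >= 2L)
  keep <- rowSums(mat <= 0) == 0L
  if (!any(keep))
    stop("no gene with nonzero counts in all libraries")
  lg <- log(mat[keep, , drop = FALSE])
  gm <- rowMeans(lg)
  apply(exp(lg - gm), 2L, median)
}

#' Normalise a count matrix by its size factors
#'
#' @param mat Gene-by-library matrix.
#' @param factors Size factors (default computed by [size_factors()]).
#' @return Matrix of normalised counts.
#' @export
normalize_matrix <- function(mat, factors = size_factors(mat)) {
  sweep(mat, 2L, factors, "/")
}

#' Aggregate gene expression over transcription units
#'
#' A transcription-unit (TU) row is the exact sum of its member genes'
#' rows; genes not in any operon are their own single-gene TU (named by
#' their locus tag).
#'
#' @param mat Normalised gene-by-library matrix.
#' @param operons Named list mapping operon id to member locus tags
#'   (`NULL` treats every gene as a singleton TU).
#' @return TU-by-library matrix.
#' @export
tu_expression <- function(mat, operons = NULL) {
  genes <- rownames(mat)
  if (is.null(operons)) operons <- list()
  members <- unlist(operons, use.names = FALSE)
  missing <- setdiff(members, genes)
  if (length(missing))
    stop("operon member missing from the matrix: ", missing[1L])
  singles <- setdiff(genes, members)
  tus <- c(operons, setNames(as.list(singles), singles))
  out <- t(vapply(tus, function(m)
    colSums(mat[m, , drop = FALSE]), numeric(ncol(mat))))
  colnames(out) <- colnames(mat)
  out
}

#' Fraction of transcription units per expression bin
#'
#' Bins TU expression per library: the lowest bin (below the detection
#' threshold) holds TUs with little or no transcription; higher bins are
#' successive multiples of the threshold.
#'
#' @param tu_mat TU-by-library matrix.
#' @param params [expression_params()].
#' @return Matrix of fractions, bins in rows (labelled by upper edge),
#'   libraries in columns; each column sums to 1.
#' @export
expression_bins <- function(tu_mat, params = expression_params()) {
  edges <- c(0, params$detection_threshold * params$bin_factors, Inf)
  labs <- character(length(edges) - 1L)
  labs[1L] <- paste0("<", edges[2L])
  for (i in 2:(length(edges) - 1L))
    labs[i] <- if (is.finite(edges[i + 1L]))
      paste0(edges[i], "-", edges[i + 1L]) else paste0(">=", edges[i])
  out <- vapply(seq_len(ncol(tu_mat)), function(j) {
    b <- cut(tu_mat[, j], breaks = edges, right = FALSE,
             include.lowest = TRUE)
    as.numeric(table(b)) / nrow(tu_mat)
  }, numeric(length(edges) - 1L))
  rownames(out) <- labs
  colnames(out) <- colnames(tu_mat)
  out
}

#' Log2 fold change between two libraries per transcription unit
#'
#' `log2((b + pseudocount) / (a + pseudocount))`, so positive values mean
#' higher expression in `library_b`.
#'
#' @param tu_mat TU-by-library matrix.
#' @param library_a,library_b Column names to contrast.
#' @param params [expression_params()].
#' @return data.frame with `tu`, `log2_fold_change`, `mean_expression`,
#'   `below_detection` (in both libraries).
#' @export
tu_contrast <- function(tu_mat, library_a, library_b,
                        params = expression_params()) {
  for (lib in c(library_a, library_b))
    if (!lib %in% colnames(tu_mat)) stop("unknown library: ", lib)
  a <- tu_mat[, library_a]; b <- tu_mat[, library_b]
  data.frame(tu = rownames(tu_mat),
             log2_fold_change = log2((b + params$pseudocount) /
                                     (a + params$pseudocount)),
             mean_expression = (a + b) / 2,
             below_detection = a < params$detection_threshold &
               b < params$detection_threshold,
             stringsAsFactors = FALSE)
}

#' Top expressed genes of one library
#'
#' @param mat Gene-by-library matrix.
#' @param library Column name.
#' @param n Number of genes (truncated to the gene count).
#' @return data.frame with `locus_tag` and `expression`, ranked; ties
#'   broken by locus tag for determinism.
#' @export
top_expressed <- function(mat, library, n) {
  stopifnot(n >= 1L)
  if (!library %in% colnames(mat)) stop("unknown library: ", library)
  v <- mat[, library]
  ord <- order(-v, rownames(mat))
  ord <- ord[seq_len(min(n, length(ord)))]
  data.frame(locus_tag = rownames(mat)[ord], expression = v[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}
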