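#' Read a genome from a FASTA file
#'
#' Reads one or more replicons, normalises lowercase bases to uppercase and
#' validates that the alphabet is restricted to A, C, G, T, N.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by replicon (first whitespace
#'   token of each header).
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in FASTA file: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate replicon name in ", path, ": ",
         names(seqs)[duplicated(names(seqs))][1L])
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty sequence for replicon ",
         names(seqs)[Biostrings::width(seqs) == 0L][1L])
  seqs <- Biostrings::DNAStringSet(toupper(seqs))
  af <- Biostrings::alphabetFrequency(seqs)
  bad <- rowSums(af[, !colnames(af) %in% c("A", "C", "G", "T", "N"),
                    drop = FALSE])
  if (any(bad > 0))
    stop("genome contains characters outside A/C/G/T/N in replicon ",
         names(seqs)[bad > 0][1L])
  seqs
}

#' Assemble a genome annotation object
#'
#' Container shared by all pipeline stages: replicon sequences, a
#' strand-aware feature table and an optional operon (transcription-unit)
#' grouping. All coordinates are 1-based inclusive.
#'
#' @param genome A [Biostrings::DNAStringSet] of replicons.
#' @param features A data.frame with columns `locus_tag`, `seqid`, `start`,
#'   `end`, `strand` (`+`/`-`), `kind` (`gene`, `CDS` or `ncRNA`).
#' @param operons Named list mapping operon id to a character vector of
#'   member locus tags, or `NULL`.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genome, features, operons = NULL) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  req <- c("locus_tag", "seqid", "start", "end", "strand", "kind")
  if (!all(req %in% names(features)))
    stop("feature table must have columns: ", paste(req, collapse = ", "))
  features <- validate_features(features, genome)
  if (!is.null(operons)) validate_operons(operons, features)
  structure(list(genome = genome, features = features,
                 operons = operons),
            class = "genome_annotation")
}

validate_features <- function(features, genome) {
  rlen <- setNames(Biostrings::width(genome), names(genome))
  if (!all(features$seqid %in% names(rlen)))
    stop("feature on unknown replicon: ",
         setdiff(features$seqid, names(rlen))[1L])
  if (any(features$start > features$end))
    stop("feature with start > end: ",
         features$locus_tag[features$start > features$end][1L])
  if (any(features$start < 1L) ||
      any(features$end > rlen[features$seqid]))
    stop("feature outside replicon bounds: ",
         features$locus_tag[features$start < 1L |
                            features$end > rlen[features$seqid]][1L])
  if (!all(features$strand %in% c("+", "-")))
    stop("feature strand must be '+' or '-'")
  if (anyDuplicated(features$locus_tag))
    stop("duplicate locus_tag: ",
         features$locus_tag[duplicated(features$locus_tag)][1L])
  coding <- features$kind == "CDS"
  len <- features$end - features$start + 1L
  if (any(coding & len %% 3L != 0L)) {
    off <- features$locus_tag[coding & len %% 3L != 0L]
    warning("CDS length not a multiple of 3 (kept): ",
            paste(head(off, 5L), collapse = ", "),
            if (length(off) > 5L) ", ..." else "")
  }
  # first base of the annotated start codon, strand-aware
  features$start_codon_pos <- ifelse(features$strand == "+",
                                     features$start, features$end)
  features <- features[order(features$seqid, features$start), ,
                       drop = FALSE]
  rownames(features) <- NULL
  features
}

validate_operons <- function(operons, features) {
  members <- unlist(operons, use.names = FALSE)
  if (anyDuplicated(members))
    stop("locus_tag in more than one operon: ",
         members[duplicated(members)][1L])
  unknown <- setdiff(members, features$locus_tag)
  if (length(unknown))
    stop("operon member not in feature table: ", unknown[1L])
  invisible(TRUE)
}

#' Read gene features from a GFF3 file
#'
#' Ingests `gene`, `CDS` and `ncRNA` rows carrying a `locus_tag` attribute
#' and validates coordinates against the genome. When both a `gene` and a
#' `CDS` row share a locus tag the CDS row wins (its interval carries the
#' start codon). An optional `operon` attribute is collected into the operon
#' map.
#'
#' @param path Path to a GFF3 file.
#' @param genome A [Biostrings::DNAStringSet] as returned by [read_genome()].
#' @return A `genome_annotation` object.
#' @export
read_annotation <- function(path, genome) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% c("gene", "CDS", "ncRNA")
  gr <- gr[keep]
  if (length(gr) == 0L) stop("no gene/CDS/ncRNA rows in ", path)
  lt <- if ("locus_tag" %in% names(S4Vectors::mcols(gr)))
    as.character(gr$locus_tag) else rep(NA_character_, length(gr))
  if (anyNA(lt) || any(lt == ""))
    stop("GFF3 row without locus_tag attribute (row ",
         which(is.na(lt) | lt == "")[1L], " of imported features)")
  df <- data.frame(locus_tag = lt,
                   seqid = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   kind = as.character(gr$type),
                   stringsAsFactors = FALSE)
  # CDS interval preferred over the gene row of the same locus
  df <- df[order(match(df$kind, c("CDS", "ncRNA", "gene"))), , drop = FALSE]
  df <- df[!duplicated(df$locus_tag), , drop = FALSE]
  operons <- NULL
  if ("operon" %in% names(S4Vectors::mcols(gr))) {
    op <- as.character(gr$operon)[match(df$locus_tag, lt)]
    hasop <- !is.na(op) & op != ""
    if (any(hasop)) {
      # members listed in transcription order (5' to 3' of the operon)
      ord <- order(ifelse(df$strand == "+", 1L, -1L) * df$start)
      keep <- ord[hasop[ord]]
      operons <- split(df$locus_tag[keep], op[keep])
    }
  }
  genome_annotation(genome, df, operons)
}

#' Write an annotation to GFF3
#'
#' @param annotation A `genome_annotation` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  df <- annotation$features
  gr <- GenomicRanges::GRanges(df$seqid,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  gr$type <- df$kind
  gr$ID <- df$locus_tag
  gr$locus_tag <- df$locus_tag
  if (!is.null(annotation$operons)) {
    op <- rep(NA_character_, nrow(df))
    for (oid in names(annotation$operons))
      op[df$locus_tag %in% annotation$operons[[oid]]] <- oid
    gr$operon <- op
  }
  GenomeInfoDb::seqlengths(gr) <-
    setNames(Biostrings::width(annotation$genome),
             names(annotation$genome))[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read an operon table
#'
#' Two-column tab-separated file mapping `operon_id` to `locus_tag`, one
#' member per row.
#'
#' @param path Path to the TSV.
#' @return Named list mapping operon id to character vector of locus tags.
#' @export
read_operons <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("operon_id", "locus_tag") %in% names(df)))
    stop("operon table needs columns operon_id, locus_tag")
  split(df$locus_tag, df$operon_id)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", length(x$genome), "replicon(s),",
      sum(Biostrings::width(x$genome)), "bp,",
      nrow(x$features), "features,",
      if (is.null(x$operons)) "no operon map" else
        paste(length(x$operons), "operons"), "\n")
  invisible(x)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

subseq_chr <- function(genome, seqid, start, end, strand = "+") {
  s <- as.character(Biostrings::subseq(genome[[seqid]], start, end))
  if (strand == "-") revcomp_chr(s) else s
}
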