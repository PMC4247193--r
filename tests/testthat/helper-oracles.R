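# Independent oracles and tiny fixture builders used across the suite.
# Oracles are deliberately written as plain loops, separate from the
# package's vectorised/GRanges-based code paths.

# brute-force TSS classifier: scan every gene x TSS pair naively
brute_classify <- function(pos, strand, features, max_up = 300,
                           flank = 100) {
  out <- character(0)
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    scp <- if (f$strand == "+") f$start else f$end
    d <- if (f$strand == "+") scp - pos else pos - scp
    same <- f$strand == strand
    if (same && d >= 0 && d <= max_up)
      out <- c(out, paste0("upstream:", f$locus_tag))
    if (same && pos >= f$start && pos <= f$end && d < 0)
      out <- c(out, paste0("iTSS:", f$locus_tag))
    if (!same && pos >= f$start - flank && pos <= f$end + flank)
      out <- c(out, paste0("aTSS:", f$locus_tag))
  }
  if (!length(out)) out <- "oTSS:NA"
  sort(out)
}

# assignment set of the package classifier in the oracle's format
pkg_classify_set <- function(tss_row, annotation, params =
                               classification_params()) {
  res <- classify_tss(tss_row, annotation, params)
  cls <- ifelse(res$class %in% c("pTSS", "sTSS", "upstream"),
                "upstream", res$class)
  sort(paste0(cls, ":", ifelse(is.na(res$locus_tag), "NA",
                               res$locus_tag)))
}

# exhaustive per-window PWM scoring via a full k-mer score table
brute_pwm_hits <- function(seq, pwm, bg, threshold) {
  w <- ncol(pwm)
  kmers <- do.call(expand.grid,
                   rep(list(c("A", "C", "G", "T")), w))
  kmer_str <- apply(kmers, 1L, function(r)
    paste(rev(r), collapse = ""))  # arbitrary but fixed enumeration
  score_of <- function(s) {
    b <- strsplit(s, "")[[1L]]
    tot <- 0
    for (k in seq_len(w))
      tot <- tot + log2(pwm[b[k], k] / bg[b[k]])
    tot
  }
  tab <- vapply(kmer_str, score_of, numeric(1))
  names(tab) <- kmer_str
  n <- nchar(seq)
  hits <- integer(0); scores <- numeric(0)
  for (j in seq_len(n - w + 1L)) {
    s <- tab[[substr(seq, j, j + w - 1L)]]
    if (s >= threshold) {
      hits <- c(hits, j); scores <- c(scores, s)
    }
  }
  data.frame(offset = hits, score = scores)
}

# naive ORF re-scan: walk every position, check start codon, walk to stop
brute_orf_scan <- function(transcript, min_codons) {
  transcript <- toupper(transcript)
  n <- nchar(transcript)
  starts <- c("ATG", "GTG", "TTG"); stops <- c("TAA", "TAG", "TGA")
  res <- list()
  for (s in seq_len(max(n - 5L, 0L))) {
    if (!substr(transcript, s, s + 2L) %in% starts) next
    j <- s + 3L
    while (j + 2L <= n) {
      cod <- substr(transcript, j, j + 2L)
      if (cod %in% stops) {
        len <- (j - s) / 3L
        if (len > min_codons)
          res[[length(res) + 1L]] <- c(start = s, end = j - 1L,
                                       codons = len)
        break
      }
      j <- j + 3L
    }
  }
  if (!length(res)) return(data.frame(start = integer(0),
                                      end = integer(0),
                                      codons = integer(0)))
  as.data.frame(do.call(rbind, res))
}

# direct median-of-ratios, written from the formula
brute_size_factors <- function(mat) {
  keep <- apply(mat, 1L, function(r) all(r > 0))
  sub <- mat[keep, , drop = FALSE]
  ref <- apply(sub, 1L, function(r) exp(mean(log(r))))
  vapply(seq_len(ncol(sub)), function(j)
    median(sub[, j] / ref), numeric(1))
}

# single-linkage clustering oracle on positions
brute_single_linkage <- function(pos, window) {
  o <- order(pos); p <- pos[o]
  grp <- integer(length(p)); g <- 1L
  for (i in seq_along(p)) {
    if (i > 1L && p[i] - p[i - 1L] > window) g <- g + 1L
    grp[i] <- g
  }
  grp[order(o)]
}

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# tiny single-gene annotation for hand-built scenarios
tiny_annotation <- function(genes, genome_seq = NULL, length = 5000) {
  if (is.null(genome_seq)) genome_seq <- random_seq(length, 0.42)
  genome <- Biostrings::DNAStringSet(genome_seq)
  names(genome) <- "chr"
  genes$seqid <- "chr"
  if (is.null(genes$kind)) genes$kind <- "gene"  # random lengths: no
                                                 # codon-multiple warning
  genome_annotation(genome, genes)
}

# coverage track from sparse position -> count maps
tiny_track <- function(n, fwd = c(), rev = c(), library_id = "lib",
                       condition = "c1", treated = TRUE) {
  fv <- integer(n); rv <- integer(n)
  if (length(fwd)) fv[as.integer(names(fwd))] <- as.integer(fwd)
  if (length(rev)) rv[as.integer(names(rev))] <- as.integer(rev)
  coverage_track(list(chr = list(fwd = fv, rev = rv)), library_id,
                 condition, treated)
}

pos_key <- function(df) paste(df$strand, df$pos)

match_within <- function(pos, strand, df, tol = 1)
  any(df$strand == strand & abs(df$pos - pos) <= tol)
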