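Package: drnatss
Title: Primary-Transcriptome Annotation from Differential RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates prokaryotic (in particular archaeal) primary
    transcriptomes from differential RNA-seq (dRNA-seq) 5'-end coverage.
    Detects transcription start sites (TSS) by comparing terminator
    exonuclease (TEX) treated and untreated libraries, classifies TSS as
    primary, secondary, internal, antisense or orphan relative to a gene
    annotation, annotates 5'-UTRs and leaderless mRNAs with start-codon
    re-assignment, discovers promoter motifs (BRE, TATA box) by
    expectation-maximisation and scans ribosome binding sites, aggregates
    expression over transcription units across growth conditions, and scores
    small-RNA sequence conservation. Ships a synthetic-data generator that
    plants TSS of every class, promoter and RBS motifs, UTR length mixtures,
    start-codon mis-annotations and condition-dependent expression programs
    with a ground-truth ledger, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
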