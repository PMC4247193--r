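---
title: "Annotating a primary transcriptome from dRNA-seq: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating a primary transcriptome from dRNA-seq: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical model behind each stage of the
pipeline, the parameters that matter, the synthetic data the package
validates itself against, and the design decisions that were genuinely
open — in the spirit of the methods vignettes of the established
RNA-seq packages.

## The measurement model

Differential RNA-seq produces, per growth condition, a pair of
libraries: one digested with terminator 5′-phosphate-dependent
exonuclease (TEX), one untreated. TEX degrades RNAs with a 5′
monophosphate — processing products and degradation fragments — while
primary transcripts, protected by their 5′ triphosphate, survive. The
data the pipeline consumes are therefore per-strand counts of read 5′
ends at each genome position. A true transcription start site (TSS) is
expected to show three signatures at one position: many reads, a sharp
step relative to the position immediately upstream in the direction of
transcription, and enrichment in the treated relative to the untreated
library. A processing site shows the first two but not the third.

## TSS detection

`call_candidates()` requires all three signatures:

* **height** — at least `min_height` (default 5) raw reads at the
  position in the treated library. This floor is deliberately applied
  to *raw* counts: it represents an absolute amount of evidence, and a
  floor on per-million-normalised heights would correspond to wildly
  different read counts depending on library depth (for libraries below
  ~10^5^ 5′ ends, a few reads per million is less than one read, which
  would make the filter vacuous and let coincident background reads
  through).
* **step factor** — normalised height divided by
  `max(upstream height, pseudocount)`, at least `min_step_factor`
  (default 2). On the minus strand "upstream" is position `p + 1`. At a
  replicon edge the upstream neighbour is undefined and the pseudocount
  is used.
* **enrichment factor** — treated height over untreated height plus
  pseudocount, at least `min_enrichment` (default 2), computed on
  reads-per-million heights so that libraries of different depth are
  comparable. The pseudocount (default 1 normalised unit) caps the
  factor when the untreated track is empty.

Candidates within `cluster_window` (3 nt) on one strand are merged by
single linkage; the representative is the position with the maximum
height, ties resolved to the most upstream position so reruns are
deterministic, and the representative keeps its own height — summing
would double-count the ±1 nt sequencing smear. Across conditions the
calls are unified as a *union* with ±1 nt tolerance: a TSS used in only
one growth condition is still a TSS.

## Classification and 5′-UTRs

Classes are purely positional, measured to the first base of the
annotated start codon, boundaries inclusive: primary/secondary within
0–300 bp upstream on the sense strand (a TSS exactly at the start codon
is an upstream TSS with a 0 nt 5′-UTR, the leaderless extreme — not an
internal one); internal strictly downstream of the start codon within
the gene; antisense within the gene or 100 bp of either end on the
opposite strand; orphan only when nothing else applies. One TSS can
hold several classes — internal-for-gene-A and primary-for-gene-B is a
real and common geometry, and both rows are reported. Among the
upstream TSS of one gene, primary is the one with the largest
normalised height summed over treated libraries; ties go to the most
upstream.

5′-UTRs are leaderless at ≤8 nt and long at 50–300 nt. The leaderless
review scans, for every leaderless mRNA and every internal TSS within
100 bp of its gene's start, the first 100 transcript bases for
alternative in-frame starts (ATG preferred, then GTG, then TTG, nearest
first, never past an in-frame stop). A candidate is accepted when a
ribosome-binding site lies 4–15 nt upstream of it inside the
transcript, *or* when adopting it moves the transcript out of the
leaderless class. The RBS spacer bounds and the or-rule are our
choices: requiring the RBS for every re-assignment would miss genuine
cases where the evidence is the implausibility of the leaderless call
itself. RBS evidence is an exact IUPAC match to GGDGRD; at most one
re-assignment is made per gene, re-assignment can only lengthen the
UTR and always stays in frame with the annotated stop, and the
procedure is idempotent — a second pass changes nothing.

## Promoter motifs

Windows cover −50..0 relative to each TSS (51 nt, the TSS base last),
reverse-complemented on the minus strand; windows truncated by a
replicon edge are excluded. Motifs are discovered by
one-occurrence-per-sequence (OOPS) expectation–maximisation against a
0-order background estimated from the windows, with a per-base
pseudocount of 0.25, convergence at ΔlogL < 10⁻⁶ or 200 iterations,
and the best of 10 random restarts. OOPS rather than a
zero-or-one-occurrence model because the windows are promoter-anchored;
the fraction of windows *without* the motif is estimated afterwards by
a score threshold instead of a mixture prior. Two refinements matter in
practice:

* **column-shift refinement** — EM can converge one column off the
  optimal register, trading an informative edge column for a flank;
  after the restarts the PWM is re-run from ±1/±2-shifted versions and
  the best likelihood kept;
* **iterative masking** — after a motif is found, each sequence's best
  site is replaced by background-sampled bases and the next motif
  searched. The sharper, less self-similar element (the BRE, width 7)
  is searched before the TATA box (width 8): TATA-like motifs are
  internally periodic, so their posterior smears across registers and
  they are more robustly found once the BRE is masked.

Scanning reports log-odds scores in bits. A window counts as carrying
the motif when its best site reaches `hit_threshold` (default 3 bits) —
deliberately permissive, because an AT-rich background partly mimics a
TATA box and stricter thresholds systematically undercount true
occurrences. Offsets are measured from the motif's 3′-most base to the
TSS; windows without a hit count toward the fraction but not the
median. With discovery on mixed windows the learned register can
legitimately be a column wider or narrower than the planted element;
motif identity is therefore decided by its median offset (TATA ≈ 23 bp,
BRE ≈ 33 bp), not by the order of discovery.

## Expression

Per-gene expression is the strand-matched count of 5′ ends within the
gene body divided by gene length in kb; positions shared by overlapping
same-strand genes count for every overlapping gene. This 5′-end proxy
is semi-quantitative — dRNA-seq libraries are enriched for 5′-terminal
sequences — and is the package's documented limitation for absolute
statements. Transcription-unit values are exact sums over operon
members; singletons are their own unit.

Three normalisations coexist, each with its domain:

* **median-of-ratios size factors** (`size_factors()`) for comparing
  libraries with similar composition. Under extreme condition-dependent
  silencing (a stationary-phase library with most units silent) the
  median gene is background-dominated and the factors are
  composition-biased — a known failure mode, which is why the
  expression bins and contrasts below do not use it blindly.
* **total-count (per-million) scaling** (`expression_matrix(...,
  per_million = TRUE)`) matching the coverage normalisation upstream.
* **raw counts**, appropriate when libraries share one effective depth
  by design, as the simulator's do.

"Little or no transcription" is a TU below `detection_threshold`
(default 150 reads per kb summed over members) — an absolute evidence
threshold applied to unscaled counts; the simulated background
(0.02 reads/nt/strand, i.e. ~20/kb/gene) and the weakest active unit
(≥500/kb/gene untreated) sit far on either side of it. Contrasts are
`log2((b + 1) / (a + 1))`; no significance testing is attempted — the
package stops deliberately short of dispersion modelling.

## Small-RNA conservation

The conservation value of a query sRNA against a subject sequence is
the number of identical nucleotides in the best local alignment divided
by the query length, times 100, retained at ≥40%. The statistic is
intentionally asymmetric: the query length is the denominator, so the
subject is never reverse-complemented in its place (both orientations
of the subject are searched instead). Alignment is Smith–Waterman with
affine gaps (+1 match, −1 mismatch, −2 gap open, −1 extend — an
identity-driven scheme in the nucleotide-BLAST tradition; a length-1
gap costs the open score alone). Sequences under 2 kb get the full
dynamic programme; longer subjects go through exact seeds of ≥10 nt
extended in a diagonal band. A database e-value cannot be defined for a
pairwise comparison, so the score and word-size gate replaces it —
documented as a replacement, not an equivalent. Identities are counted
over aligned columns only; gap columns are non-identical.

## The synthetic study design

`simulate_genome()` builds the genome the analysis assumes: genes of
152–400 codons at 42% GC grouped into transcription units (61%
singletons, multi-gene operons averaging ~3 genes), each unit led by a
promoter pad carrying a TATA box (median 23 bp upstream of the TSS,
Gaussian jitter σ = 2) and a BRE 10 bp further upstream, both planted
in 90% of units with 93% per-base consensus fidelity. 5′-UTR lengths
come from a three-component mixture — 14% leaderless (0–8 nt,
uniform), 20% long (50–300 nt, discretised log-normal, median 103 nt,
48% GC), the rest a discretised log-normal over 9–49 nt placed so the
population median is 16 nt. Secondary TSS (25% of units, at 40% of the
primary's depth) draw their UTR independently from the same mixture so
the combined pTSS+sTSS distribution keeps those targets. An RBS
hexamer matching GGDGRD is planted for half of all mRNAs (spacer
4–12 nt). Internal (0.3/gene) and antisense TSS (0.5/gene; 58% within
150 bp of a start or stop codon) are constitutive; orphan TSS sit in
dedicated 800 bp gene deserts. Mis-annotated genes are leaderless genes
re-annotated to a GTG with the true ATG 2–3 codons downstream and an
RBS overlapping the GTG. All planted fractions are quota-sampled, not
Bernoulli-sampled: the configured value is the planted value up to
rounding, so recovery tolerances test the pipeline rather than the
generator's sampling noise.

Expression programs assign each unit a clipped log-normal level
(1–16×) silenced per condition at the configured fractions (28%
sulfur-exponential, 87% stationary, 35% in the two pyruvate
conditions), with every unit kept active in at least one condition so
the detectable universe is well defined, and one reciprocal
"sulfur-switch" operon pair swinging 16-fold (|log2FC| = 4) between
the pyruvate and pyruvate-plus-sulfur conditions.

Coverage is Poisson throughout: peaks of expected depth 40 × level at
primary TSS (auxiliary classes at 0.75×, secondary at 0.4×), ±1 nt
smear with probability 0.1 per read, processing-site peaks only in
untreated libraries, gene-body 5′ ends at 0.5 reads/nt/level in
untreated libraries of which TEX digestion leaves 5% in treated ones
(the carry-over of an efficient digestion — at 15% the body reads of
strongly expressed operons start to produce spurious TSS calls, which
the detector's documented near-zero false-call rate excludes), primary
peaks retained at 30% in untreated libraries (TEX enriches, it does
not create), and uniform background of 0.02 reads/nt/strand.

What the generator does **not** emulate: sequence-composition biases of
ligation and reverse transcription, RNA secondary structure and its
effect on TEX efficiency, transcript 3′ ends and terminators, partial
TEX digestion varying per transcript, and real annotation errors beyond
the planted start-codon pattern. Passing the recovery suite therefore
demonstrates the pipeline's correctness under its stated model, not
performance on any particular real library.

## Validation problem sizes and numerics

The self-validation suite uses the study design at sizes chosen to make
each statistic well estimated: the default 200-gene genome (~109 units,
~320 planted TSS) for detection, classification and expression; 1,000
genes (guaranteeing >500 mRNA 5′-UTRs) for the UTR mixture; 600 genes
(>300 primary TSS windows) for motif offsets; 650 genes (>300
antisense TSS) for terminus enrichment; 420 genes with 25 planted
mis-annotations for the start-codon review; 200 random pairs of ≤30-mers
against an independent dynamic-programming oracle for the aligner.

Numerical conventions, in one place: coordinates are 1-based inclusive
end to end, the native convention of R and Bioconductor ranges —
adopting a 0-based half-open internal convention inside an R package
would add a conversion at every boundary rather than remove one.
Replicons are linear; windows truncate at ends. Duplicate wiggle
positions are an ingestion error, not a sum. CDS lengths that are not
codon multiples warn and are kept (real annotations contain
pseudogenes). All ties anywhere (cluster representatives, primary
ranking, top-expressed lists) break deterministically. Every stochastic
step — the generator, coverage, EM restarts, masking — takes an
explicit seed, restores the caller's RNG state, and reproduces
byte-identical output on reruns; reverse-complementing the genome and
swapping every strand label yields outputs identical under coordinate
reflection.
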