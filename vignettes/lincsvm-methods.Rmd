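---
title: "lincsvm: model, features and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lincsvm: model, features and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lincsvm)
```

# The problem

De novo transcriptome assembly yields thousands of transcript models, and
long intergenic non-coding RNAs (lincRNAs, > 200 nt, between protein-coding
loci, no protein product) must be separated from protein-coding transcripts
(PCTs). Alignment-based coding-potential methods are accurate but orders of
magnitude too slow for assembly-scale input, and protein-database methods
misclassify novel PCTs that are not yet in the database. lincsvm instead
uses a small set of features computable from the transcript structure, the
genome sequence and a precomputed per-base conservation track, and a binary
RBF-kernel SVM with the lincRNA class positive.

# Features

Ten slots in three classes are declared by `feature_config()`; the fixed
order is conservation, ORF length, ORF proportion, then the k-mers.

**Mean exonic conservation.** Per-base conservation scores (phastCons-like,
in [0, 1]) are averaged over every exonic genomic position. Positions
missing from the track contribute **0 rather than being skipped**: gaps in
such tracks usually mean the base is unalignable across species, which is
evidence of non-conservation, and the rule keeps the denominator equal to
the spliced transcript length. The consequence is that a transcript
entirely absent from the track scores 0, not NA.

**ORF length and proportion.** The original tooling delegated ORF calling
to an external binary whose scoring is not documented; lincsvm therefore
pins a deterministic, oracle-checkable definition: the longest substring
starting `ATG` and ending at the first in-frame stop codon, stop included
in the length, over the three forward frames of the already 5'→3'-oriented
transcript (the reverse strand is never scanned — strand is resolved during
sequence extraction). Ties go to the 5'-most start. A codon containing `N`
aborts the candidate entirely: an `N` makes the codon's identity — and in
particular whether it is a premature stop — unknowable, so no ORF is
claimed across it. No complete ORF means both ORF features are 0, which
keeps the "low-quality ORF" signal monotone without inventing partial-ORF
rules. ORF proportion is ORF length divided by transcript length, so it is
1 exactly when the transcript is a single complete ORF.

**k-mer frequencies.** Overlapping windows sliding by one; the denominator
counts only windows free of `N`, so frequencies stay comparable between
masked and unmasked sequence. The default word list is GC, CT, TAG, TGT,
ACG, TCG. The source material describes *seven* composition features but
names only these six; the seventh is unrecoverable, so the default is the
six named words and the list is configurable — no seventh word is guessed.

**Scaling.** Features are min–max scaled to [0, 1]; parameters are learned
on the training set only, stored in the model file, and out-of-range values
at prediction time are clamped. Constant features scale to 0.

# Training protocol

* **Grid search.** `(C, γ)` over the conventional LIBSVM grid
  (`C ∈ 2^{-5,-3,…,15}`, `γ ∈ 2^{-15,-13,…,3}`), each cell scored by
  stratified k-fold cross-validated accuracy (default 5 folds, matching the
  default of the reference grid-search script) on a seed-deterministic
  subsample of at most 5,000 instances. Ties break to smaller `C`, then
  smaller `γ` — the least complex model among equals. The final model is
  additionally reported with 10-fold cross-validation, the protocol's
  stated fold count.
* **Leakage control.** Within every cross-validation fold the scaler is
  refitted on that fold's training part only.
* **Solver.** The C-SVC dual is solved by an in-package SMO (C++) with
  maximal-violating-pair working-set selection and the standard stopping
  rule at tolerance **1e-3** (pinned). The solver is an exchangeable
  component behind the dual-coefficient RBF decision-function contract; no
  external SVM library is required. Iterations are capped at
  `max(20000, 100·n)`; a capped run returns the current (approximate)
  iterate, which only matters in pathological grid corners and is then
  penalized by its own cross-validation score.
* **Calibration.** The non-coding score is a Platt sigmoid
  `1/(1 + exp(A·d + B))` fitted by the robust Newton procedure on
  out-of-fold decision values from an internal stratified 5-fold split —
  the same construction the reference SVM implementation uses for
  probability estimates, and the reason a score of ~0.95 behaves like ~95 %
  probability of being non-coding. With fewer than 2 instances per class
  the sigmoid falls back to in-sample decision values with a warning.
  The classification threshold is fixed at score 0.5 (configurable in the
  CLI); the label is `noncoding` iff the score reaches the threshold.
* **Determinism.** Every random choice (grid subsample, fold assignment,
  calibration split, corpus generation, balanced splits) flows from one
  user-supplied integer seed, and the caller's RNG state is restored
  afterwards. Identical seeds and inputs reproduce output files byte for
  byte.

# Model files

One versioned JSON file embeds the feature configuration, scaler, SVM dual
solution, Platt parameters and label mapping. Numeric payloads are encoded
as 17-significant-digit decimal strings: R's default numeric-to-JSON
serialization keeps only 15 significant digits, which is *not* enough to
round-trip doubles, while `%.17g` plus correctly-rounded `strtod` is —
save → load → predict is bit-exact. Loading rejects unknown format or
version tags and truncated files.

# Evaluation

Sensitivity `TP/(TP+FN)` and specificity `TN/(TN+FP)` follow the field's
orientation for this task (lincRNA = positive). MCC uses the standard
four-marginal formula; a zero marginal yields 0 with a warning (the usual
convention; well-formed evaluations never hit it). Printed percentages are
rounded half-up to one decimal so they can be compared bit-stably against
tabulated values. ROC curves sweep distinct score values descending with
tied scores grouped into a single step, which makes the trapezoidal area
*exactly* equal to the rank-statistic (Mann–Whitney) AUC — the test suite
asserts agreement within 1e-12 rather than near-equality.

# Coordinate conventions

Internally everything is 0-based half-open. BED is taken unchanged; GTF/GFF
(1-based closed) and WIG (1-based) are converted at parse time. Unstranded
(`.`) records are treated as `+` with a warning — some orientation is
needed to compute sequence features, and rejecting legal BED would be
worse. IUPAC ambiguity codes are masked to `N` rather than rejected, with
the `N` semantics above. Overlapping conservation records resolve
last-record-wins, with a warning, so input order defines the result.

# The synthetic corpus

`generate_corpus()` exists so the full pipeline — parsing, extraction,
features, training, prediction, evaluation — runs and is tested with no
external downloads. Per class it emulates exactly the properties the
features read:

* **Coding** transcripts embed one complete ORF (default 240–1200 nt,
  uniform over multiples of 3, at least 30 nt left for UTRs) with internal
  codons drawn from the 61 sense codons weighted toward GC-rich codons
  (strength 0.8) — never a premature in-frame stop — inside uniform UTRs;
  exonic conservation is drawn per base from a normal with mean 0.65
  (sd 0.15) clamped to [0, 1].
* **Non-coding** transcripts are random sequence with composition shifted
  toward A/T (strength 0.25) and conservation mean 0.12; spurious short
  ORFs arise naturally and are deliberately not suppressed.
* Transcript lengths are uniform on 300–2000 nt (inside the > 200 nt
  curation regime), 1–5 exons, introns 60–500 nt, placed without overlap
  ("intergenic") on 8 synthetic chromosomes with 200–500 nt gaps, random
  strand. The BED12 file is the primary annotation and a GTF mirror is
  emitted, so both parsers are exercised against the same truth.
* Conservation scores are rounded to 3 decimals *before* entering the
  in-memory track so that the serialized bedGraph and the in-memory object
  agree exactly.

Default class sizes are 400 + 400 so that the balanced half-split yields
200 + 200 training and 200 + 200 held-out transcripts. The defaults were
chosen once to represent a clearly separated two-class world at desk scale
and are not tuned against test outcomes.

**The null configuration.** Setting `noncoding_embed_orf = TRUE` routes
non-coding transcripts through the same constructor as coding ones (same
ORF embedding, same codon bias), so with equal conservation means the two
classes are statistically exchangeable by construction. This is the
supported way to demonstrate that cross-validation accuracy collapses to
chance when no signal exists — a guard against protocol leakage.

**What a green test does not establish.** The generator draws per-base
conservation independently (real conservation is strongly autocorrelated),
uses uniform UTRs, length-independent exon counts, a single global codon
bias, and classes far better separated than curated human/mouse corpora.
Perfect held-out recovery here validates the pipeline's correctness, not
the accuracy obtainable on real annotation; published accuracies depend on
external gold-standard data and are checked only as formula-fidelity
(recomputing tabulated percentages from tabulated count pairs), never
claimed as reproduced measurements.

# Curation operations

The gold-standard-style filters are generic: a strict `> min_nt` length
filter; `exclude_overlap`, dropping candidates with ≥ 1 bp same-strand
exonic overlap with a reference annotation (strand-aware, because lincRNAs
are defined against same-locus coding annotation and antisense transcription
is a separate category); and `require_consistent`, keeping candidates whose
id or exact exon chain appears in the reference. Whether the original
curation matched by identifier or by overlap is not recorded, so both modes
are provided without claiming either is the original. "Roughly equal"
negatives in the balanced split is implemented as exactly equal
(deterministically), with the remainder held out for testing.

# Known limitations

* Only the three forward frames of the oriented transcript are scanned for
  ORFs; non-ATG starts and stopless ORFs are not considered (declared
  substitute for an undocumented external ORF caller, not a claim about
  it).
* The default feature set carries six composition words where the source
  describes seven (see above).
* Text WIG/bedGraph is the required conservation input; binary bigWig is
  out of scope.
* The solver holds the full kernel matrix; training is intended for the
  protocol's ≤ 5,000-instance grid-search regime, not for hundreds of
  thousands of instances.
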