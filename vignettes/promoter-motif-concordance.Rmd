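---
title: "Methods: promoter motif scanning and motif–regulation concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter motif scanning and motif-regulation concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uprshift)
```

# The analysis model

`uprshift` formalises a common regulatory-genomics argument: a
transcription factor (here Atf4, the bZIP factor translationally induced
during ER stress) is proposed to drive a set of expression changes because
its binding motifs are over-represented in the promoters of the responding
genes. The package decomposes that argument into four testable stages —
classification, scanning, concordance, and (optionally) qPCR validation —
and ships a synthetic-data generator that exercises all of them against
known ground truth.

## Regulation classification

Input is a per-gene pair of positive expression levels (control, stress) in
arbitrary but common units; the pipeline deliberately starts *after* array
or qPCR summarisation (no probe-level preprocessing). With
FC = stress/control:

* `up` when FC ≥ 2,
* `down` when FC ≤ 1/1.5,
* `unchanged` otherwise.

Both thresholds are **inclusive** because the source convention is phrased
as "at least n-fold"; the boundary behaviour is unit-tested. Thresholds are
recorded in every call object so downstream tables are self-describing.
Classification is scale-invariant (only the ratio matters), which is also a
tested property. Whether "significantly up-regulated" should instead mean a
statistical test across array replicates is genuinely open; the package
uses the fold-change criterion and documents that choice here.

## Promoter windows

A promoter window spans `upstream_bp` (default 2000) bases before the TSS
plus `downstream_bp` (default 500) bases starting **at** the TSS base, in
the direction of transcription; minus-strand windows are
reverse-complemented so "upstream" is always left of `tss_offset`. The
window therefore has exactly `upstream_bp + downstream_bp` bases away from
contig edges; truncation at an edge shifts `tss_offset` and never pads.
Internally all coordinates are 0-based half-open; GFF3 (1-based inclusive)
and BED (0-based half-open) are converted at the I/O boundary, which is the
only place an off-by-one can hide and is pinned by dialect-specific tests.
A gene may own several TSSs (alternative transcripts); each yields its own
window and gene-level queries take the union, deduplicating hits on their
genomic footprint.

## Motif scanning

Motifs are literal degenerate IUPAC consensi — the CRE core `TGACGT` and
the Atf4 element `TTKCATCAK` (= TT(G/T)CATCA(G/T), four concrete words) —
matched without scores or mismatches, which is exactly the method being
reproduced; PWMs are a deliberate non-goal. Matching rules that needed a
decision:

* **Both strands by default.** bZIP sites are quasi-palindromic and
  functional in either orientation; the reverse complement `ACGTCA` of the
  CRE core occurs inside the full palindrome `TGACGTCA`. A `strands` flag
  restricts scanning when needed.
* **Subject `N` matches nothing** except a motif letter `N` — an unknown
  base is never evidence for a site.
* **Overlapping occurrences are all reported**; the output is a site list,
  not a coverage measure. Ties at one offset sort forward-before-reverse.
* Reverse-strand hits are reported at the 5'-most forward offset, and
  `matched` is stored in promoter-forward orientation (its reverse
  complement satisfies the consensus).

The scanner compiles a consensus to a character-class regular expression
evaluated with zero-width lookahead (so overlaps are kept). Its contract is
enforced by an independent brute-force oracle in the test suite — every
window tested by substring membership in the expansion set — on 100 seeded
random sequences of 50–10,000 bp, plus strand-involution and
hit-monotonicity properties.

## Reporter-style mutagenesis

`mutate_sequence()` applies point substitutions and interval deletions
(0-based, validated, right-to-left so input coordinates stay meaningful;
overlaps involving a deletion are rejected) and returns a new sequence.
This mimics the reporter experiments in silico: two point mutations in a
CRE, or deletion of a TTGCATCAG footprint, must remove exactly that hit on
rescan and nothing else. The exact pair of point mutations used
historically in mammalian reporters is not specified anywhere we can rely
on, so edits are explicit user input rather than baked in.

## Concordance: the 2×2 exact test

Genes are partitioned by (up vs not-up) × (≥1 site vs none). The source
analysis reports only the counts (6 of 7 up genes with a site; 1 of 4
non-up genes); the exact test is this package's formalisation of
"concordance". The two-sided p follows the **probability-ordering**
convention — the sum over all tables with the observed margins of
hypergeometric probabilities ≤ the observed table's (relative tie tolerance
1e-7) — computed by explicit enumeration over the feasible range of cell
`a` in log space. That convention is dominant (and matches
`stats::fisher.test`) but differs from "double the one-sided p", hence this
note. The odds ratio is the sample (a·d)/(b·c), not the conditional MLE —
simpler and adequate for a descriptive 2×2 summary; +Inf when b·c = 0 with
a·d > 0; any zero margin flags the result degenerate with p = 1. For the
(6, 1, 1, 3) table the enumeration gives p = 29/330 ≈ 0.0879, a frozen
value recomputed by an independent `dhyper` oracle before being trusted.

## qPCR model

Relative expression is efficiency^(Ct_ref − Ct_target) against a
housekeeping reference (RpL19 in the motivating experiments), with
efficiency default 2.0 (perfect doubling; configurable because no
standard-curve correction is assumed). Technical replicates are paired by
replicate id when target and reference ids match; otherwise each target
replicate is normalised by the reference-condition mean Ct — the
technical-triplicate design is ambiguous on pairing, so both routes exist
and the paired route is preferred. Summaries are taken on the **log scale**
(geometric mean; SE of log-levels mapped to the linear scale by the delta
method) because Ct differences are log-scale by construction. Optional
calibration divides all conditions by one condition's mean (control = 1);
calibration is idempotent. Group comparisons use a paired Student's t-test
implemented from the formula (t = mean(d)/(sd(d)/√n), df = n − 1) with
degenerate-variance conventions flagged explicitly. No multiple-testing
correction is applied by default (per-gene tests only); `stats::p.adjust`
composes trivially where a family of tests is formed.

# The synthetic world

The generators state one fixed world; their defaults were chosen once and
are not tuned against test outcomes.

* **Backgrounds**: one contig per gene, i.i.d. bases with
  P(G) = P(C) = gc/2, default GC 0.43 (typical fly euchromatin); genes
  alternate between + and − strands so strand handling is always exercised.
  Any candidate window containing a forbidden motif on either strand is
  rejected and resampled (capped), so scans of unplanted backgrounds return
  exactly zero hits by construction.
* **Planting** resolves degenerate letters uniformly at random (seeded) and
  writes reverse complements for minus-strand placements. Because a planted
  word's junction with the background can, rarely, create an unintended
  occurrence, planting verifies by rescanning and resamples until the
  recovered set equals the placement list exactly — this keeps
  "recovers exactly the planted sites" a construction guarantee rather than
  a probabilistic one.
* **Expression**: control = base·2^ε₁, stress = base·FC·2^ε₂ with
  ε ~ N(0, σ_log2) independent — log-normal multiplicative noise, the error
  structure of array/qPCR levels. At σ = 0 the planted labels are recovered
  exactly; at FC = 4 and σ = 0.25 the miss probability has the closed form
  P(Δ < −1) with Δ ~ N(0, σ√2), against which the simulated rate is checked
  within 3 Monte-Carlo SDs over 10,000 replicates.
* **Ct tables**: Ct_target = Ct_base − log_eff(level) + η,
  Ct_ref = Ct_base + η, η ~ N(0, σ_Ct) per well — the exact inverse of the
  quantification model, giving a zero-noise round-trip identity and the
  error-propagation check SE(log2 level) = σ_Ct·√2/√n.
* **Default cohort**: 11 genes — 7 up (FC 4, chosen as a comfortably
  supra-threshold effect of the magnitude seen for glycolytic mRNAs), 6 of
  them carrying one site; 4 unchanged (FC 1), 1 carrying a site — the same
  table shape as the motivating 7-up/4-not-up analysis, so the association
  stage reproduces (6, 1, 1, 3) end-to-end.

What a green synthetic run does **not** establish: the generator has no
probe effects, no correlated noise between genes, no chromatin context, no
motif clustering or composition bias beyond uniform GC — so it validates
the *computations*, not the biological claim, and says nothing about
annotation-release sensitivity of real-genome TSS coordinates.

# Numerical and degenerate-input choices

* Fisher enumeration runs in log space (`lchoose`) with ties at relative
  1e-7; pmf normalisation to 1e-12 is a tested invariant.
* Zero-variance paired differences: p = 1 when the mean difference is 0,
  p = 0 otherwise, both flagged `degenerate` rather than silently NaN.
* Single qPCR replicates report dispersion 0 with a warning instead of NA.
* A motif longer than its subject yields an empty hit list, not an error;
  empty promoter-window sets are an error.
* Windows entirely off-contig, unknown strand symbols, TSS < 1, duplicate
  FASTA ids and non-IUPAC residues are hard errors at the I/O boundary;
  IUPAC ambiguity letters other than N in subjects are folded to N (they
  can then never match, consistent with the subject-N rule).

# Known limitations

* Literal consensus matching cannot rank sites or tolerate mismatches;
  that is faithful to the method being packaged, not a recommendation.
* The real-genome reproduction (FlyBase annotation, specific glycolytic
  gene set) requires a genome download and is out of scope for the offline
  test suite; annotation-release drift would move TSS coordinates and hence
  counts.
* The qPCR dispersion is a delta-method approximation, adequate for the
  small log-scale SEs of technical triplicates but not for wildly noisy
  replicates.
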