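---
title: "Methods: nucleosome footprinting, methylation deconvolution and donor-fraction estimation in cfDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleosome footprinting, methylation deconvolution and donor-fraction estimation in cfDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfdnatools)
```

Cell-free DNA is released largely by dying cells and is degraded by
nucleases everywhere except where proteins — above all nucleosomes —
protect it. Two orthogonal layers of information survive in a sequenced
cfDNA library: *where* fragments start and end (nucleosome footprints) and
*which cytosines are methylated* (tissue-of-origin marks). This package
analyzes both layers downstream of alignment, plus the donor-allele layer
available in transplant recipients. This vignette explains the models, the
parameters that matter, the numerical choices, and what the synthetic
benchmarks do and do not demonstrate.

## Fragment model

A fragment is a genomic interval in BED convention: 0-based, half-open
`[start, end)`; its endpoints are the positions `start` and `end − 1`.
Strand is not stored — nuclease protection is strand-agnostic — and enters
only through region orientation during TSS aggregation. Conversion of
paired-end alignments to intervals (leftmost start of the proper pair to
rightmost end) is expected upstream; the package consumes BED3+.

Length classes are half-open: medium `[140, 200)` bp, long `[200, 501)` bp.
The 200-bp boundary is conventionally quoted as the upper end of the medium
class and the lower end of the long class; we assign it to the long class so
the two classes partition `[140, 500]` disjointly. Medium fragments are the
mononucleosomal population (~167 bp peak); long fragments are di-nucleosomal
and degraded material.

## Windowed protection score

For window size $n$ (even; 120 by default, 200 for long-fragment analyses)
and window $W(p) = [p - n/2,\, p + n/2)$:

$$\mathrm{WPS}_n(p) = \#\{\text{fragments spanning } W(p)\} -
  \#\{\text{fragments with} \ge 1 \text{ endpoint in } W(p)\}$$

Two conventions need fixing because the verbal definition leaves them open:

* **Disjointness.** A fragment whose endpoint falls exactly on a window
  edge would satisfy both "spanning" (with a non-strict inequality) and
  "endpoint inside". We give endpoint status priority: a fragment counts
  +1 only when it covers the window strictly beyond both edges
  (`start < p − n/2` and `end > p + n/2`). The two counted sets are then
  disjoint by construction, and $|\mathrm{WPS}(p)|$ can never exceed the
  number of fragments overlapping $W(p)$.
* **Sign.** We use the protection-positive orientation (spanning minus
  endpoints): nucleosome-protected positions score high, accessible
  positions low. This is the orientation in which TSS plots show a negative
  nucleosome-free region and positive nucleosome peaks.
* **Per-fragment counting.** A fragment with both endpoints inside the
  window contributes −1 once, not twice: the score counts fragments, not
  endpoints.

The implementation accumulates interval contributions in a difference
array, which is $O(F + L)$ for $F$ fragments over $L$ positions; the test
suite pins it, integer for integer, to a direct per-position evaluation of
the definition.

Two normalizations follow, in this order:

1. **Count normalization** divides by the number of fragments overlapping
   the analyzed region (any overlap, after length filtering), controlling
   sequencing-depth differences. A region with zero fragments yields an
   all-zero track plus a warning rather than an error, so batch runs
   survive empty regions. No further cosmetic rescaling is applied.
2. **Running-mean centering** subtracts the mean score within ±500 bp
   (window truncated at region edges), flattening broad coverage trends to
   a running 1-kb mean of zero. This is the track the peak caller consumes.

For aggregation around anchors (TSS), each anchor window (±5 kb by default)
is scored raw, count-normalized with its own denominator, oriented so that
positive offsets point downstream of transcription, and averaged with equal
weight; the running-mean centering is applied once, to the merged average.
For single-region peak calling the centering is applied to the single
normalized track instead — matching the use of unmerged, normalized data
for peak detection. Minus-strand anchors use the genomic window
`(pos − flank, pos + flank]` reversed, which makes the offset grid
`−flank..flank−1` identical for both strands and makes a minus-strand
aggregate the exact mirror of the equivalent plus-strand construction.

## Nucleosome peak calling

Candidate segments are maximal runs of positive scores in which up to 4
consecutive non-positive values do not interrupt the run; a 5th terminates
it. We treat *zero* as non-positive — a zero score carries no protection
evidence — and count gap positions toward the segment span. Segments
spanning 50–450 bp are retained (shorter ones are noise; longer ones are
unresolved multi-nucleosome stretches and are discarded rather than split).
Within a segment, the contiguous run of scores at or above the segment's
own median with the largest score sum wins; the peak is the middle position
of that run. Deterministic tie-breaks: non-strict ≥ on the median (so a
constant segment still yields a peak), leftmost run on equal sums, lower
middle on even run lengths.

Interpeak distances above 1 kb are discarded as non-adjacent. The
Mann-Whitney comparison of IPD distributions enumerates all
$\binom{n_1+n_2}{n_1}$ rank assignments when $n_1 + n_2 \le 12$ without
ties (two-sided $p = 2\min(P(U \le u), P(U \ge u))$, capped at 1) and
otherwise uses the normal approximation with midranks, tie correction and
continuity correction. The suite cross-checks both branches against
`stats::wilcox.test`.

## Nucleosome positioning signal

On an aggregate WPS$_{120}$ track, with inclusive integer offsets in
transcription orientation,

$$\mathrm{NPS} = \sum_{i=135}^{185} s(i) - \sum_{i=10}^{60} s(i),$$

the +1-nucleosome window minus the nucleosome-free-region window (51
offsets each; the synthetic track with $s = 1$ on the first window and $-1$
on the second scores exactly 102). The statistic is linear in the track.
The offsets are calibrated to a 120-bp WPS window; other window sizes need
other offsets, which is why both windows are arguments.

Gene bins rank genes by expression in a chosen tissue (descending TPM),
with mean TPM across all tissue columns as the secondary key for exact ties
and gene id as the final tie-break — a total sort key, so binning is
deterministic. Zero-expression genes are split out by default rather than
binned. Tissue-enriched sets first restrict to genes strictly below 0.5 TPM
in whole blood. For NPS-vs-rank we report both Pearson and Spearman
correlations: reported correlations of this kind are conventionally Pearson
on bin summaries, but the monotone claim is Spearman's, so both are given.

## Methylation summarization and deconvolution

Call ingestion auto-detects the two common extractor dialects (6-column
coverage files, 7-column cytosine reports), normalizes positions to
0-based, and warns when a reported percentage contradicts its counts by
more than one percentage point. Locus methylation pools counts —
$\sum m_i / \sum (m_i + u_i)$ over CpG-context records inside the locus —
rather than averaging per-CpG percentages; pooling weights every read
equally and is robust at the shallow depths typical of cfDNA. Both strands
of a CpG dyad pool naturally. Loci under the coverage floor (default 1) are
emitted as missing and dropped pairwise downstream; nothing is imputed.

Deconvolution solves

$$\min_X \|A X - m\|^2 \quad \text{s.t.} \quad 0 \le X_j \le 1,\;
\sum_j X_j \le 1$$

with $A$ the reference atlas (loci × tissues; 7,890 informative CpG loci ×
25 tissues in the canonical published atlas) and $m$ the measured locus
fractions. The inequality (rather than equality) on the sum is deliberate:
tissues absent from the reference — bone, for example — contribute cfDNA
that no column can absorb, and that mass surfaces as
`unknown_fraction = 1 − ΣX` instead of being smeared across unrelated
tissues. Nonnegativity is imposed explicitly: negative tissue fractions are
physically meaningless, and leaving them to a solver default would make the
result solver-dependent.

The solver is accelerated projected gradient descent (FISTA) with an exact
Euclidean projection onto the box-plus-simplex set (clamping, then a
bisection on the simplex shift), all-zero initialization, a function-value
restart on non-monotone steps, step size $1/L$ with $L$ the largest
eigenvalue of $A^\top A$, and a relative objective tolerance of $10^{-12}$
(cap 50,000 iterations; 25-tissue problems converge in tens of iterations).
It is deterministic, requires at least as many usable loci as tissues
(overdetermined system), and is validated three independent ways:
constructed-truth recovery ($10^{-3}$ elementwise on noiseless mixtures),
comparison against `stats::constrOptim` on small problems, and KKT-style
dominance over the zero vector and all single-tissue vertices. When a
reference column is all-constant relative to the others the optimum can be
non-unique (the classic case: an all-zero column fits any coefficient
without changing the objective); the deterministic solver then returns the
minimum-coefficient solution, and only the identified components are
asserted in tests.

Spike-in QC: conversion efficiency is one minus the methylated fraction
over all cytosines of the unmethylated lambda control; retention is the
methylated CpG fraction of the fully methylated pUC19 control.

## Graft-derived cfDNA fraction

Only A>T and T>A transversions are usable in converted libraries: cytosine
conversion itself produces C→T (and G→A on the complement) signal, so any
variant involving those changes is confounded. Informative positions
require a donor variant call (hom-alt or het) at such a transversion and a
reference call in the recipient; positions with recipient variant calls, or
not covered in the recipient data, are excluded with a reason code, and the
estimator provably ignores excluded positions. When only raw recipient
fractions are available, an alt fraction ≥ 0.2 counts as a variant call —
low enough to catch true heterozygotes sampled shallowly, high enough not
to be triggered by the graft-derived fraction itself at realistic levels.

The estimate is the mean per-position donor-allele fraction, doubled in
het-donor mode (only half the donor chromosomes carry the variant) and
capped at 1. The 95% CI is $1.96\,\mathrm{sd}/\sqrt{n}$ over the
post-doubling per-position fractions — a normal approximation across
positions, chosen because per-position depth varies and the
across-position spread captures both binomial and positional variance.
Simulation at 1,000 positions and depth 30 shows ~95% empirical coverage
for both donor modes. A minimum depth of 10 reads per position (default)
keeps single-read positions from dominating the average.

## Synthetic-data layer

The generators are pure functions of their parameters and a mandatory
seed; they define the conditions under which the pipeline is tested.

* **Phased fragments**: nucleosome dyads on a regular grid (default
  spacing 190 bp, the typical cfDNA nucleosome repeat), optionally
  excluded from a nucleosome-free interval; each fragment's midpoint is a
  uniformly chosen dyad plus Gaussian jitter (`dyad_jitter_sd`, the
  phasing-strength dial used by the benchmarks: 0 = perfect phasing, 80 ≈
  unphased); lengths are normal 167 ± 10 bp truncated to [100, 500],
  mimicking the mononucleosomal peak. The TSS benchmark layout places the
  anchor at the NFR edge with the +1 dyad at offset +160, inside the
  +135..+185 NPS window.
* **Methylation mixtures**: reference entries drawn Beta(0.3, 0.3) —
  bimodal, as informative CpGs are — mixed with known coefficients and
  sampled binomially at a chosen depth, so $E[m] = A x$ exactly.
* **Allele pileups**: binomial alt counts at expected fraction $f$ (hom
  donor) or $f/2$ (het donor).

These emulate the statistical structure the estimators assume — and only
that. They do not model GC or mappability bias, fragment-length/position
coupling, end-motif chemistry, sub-nucleosomal footprints, CNV, or
between-locus depth variation. A green synthetic benchmark therefore
demonstrates correctness of the computation, not robustness to every
artifact of real libraries.

## Problem sizes and determinism

The shipped tests and the acceptance script use desk-scale sizes chosen to
exercise every code path with comfortable statistical margins: 200 random
WPS instances of ≤100 fragments over 2-kb regions; 50,000 fragments per
phasing level for the NPS benchmark; 5 tissues × 200–300 loci and 20 seeds
for deconvolution; 500 replicates of 1,000 positions at depth 30 for CI
calibration; 1,000 replicates for the rank-sum size check. Every random
draw is seeded; the command-line interface writes byte-identical output
for identical seeds.

## Known limitations

Genome-scale WPS tracks are supported but not optimized (pure R difference
arrays; no compiled kernel or bigWig output). The deconvolution reference
must share locus ids with the sample — no liftover or reference
harmonization across conversion chemistries is attempted. Long (>450 bp)
positive WPS segments are discarded, not split, so densely packed tandem
nucleosomes may be under-called. The rank-sum exact branch is limited to
$n_1 + n_2 \le 12$ without ties. The graft estimator assumes informative
positions are independent; linked positions would narrow the reported CI
below its true width.
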