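# cfdnatools

Joint nucleosome footprinting and methylation profiling of cell-free DNA
(cfDNA), for researchers analyzing plasma or urine sequencing libraries that
preserve both fragmentation and cytosine-conversion information (e.g.
enzymatically converted whole-genome libraries). The package takes
post-alignment, tabular inputs — fragment intervals (BED), per-cytosine
methylation calls (coverage or cytosine-report dialect), expression tables,
genotype tables and allele pileups — and returns tibbles, so every analysis
chains with the pipe.

## What it computes

**Windowed protection score (WPS).** For each genomic position *p* and an
*n*-bp window *W(p) = [p − n/2, p + n/2)*,

```
WPS_n(p) = #(fragments spanning W(p)) − #(fragments with ≥1 endpoint in W(p))
```

so nucleosome-protected positions score positive and nuclease-accessible
positions negative. Tracks are normalized to the fragment count of the
analyzed region (depth control) and centered on a running ±500 bp mean.
Strand-aware aggregation around transcription start sites (TSS) yields the
familiar footprint: a negative nucleosome-free region (NFR) and a strong
+1-nucleosome peak.

**Nucleosome peaks and spacing.** Peaks are called from contiguous runs of
positive WPS 50–450 bp long (tolerating ≤4 consecutive non-positive values),
taking the middle of the highest-sum run of scores at or above the segment
median. Interpeak distances (IPDs, ≤1 kb) measure nucleosome spacing;
`rank_sum_test()` compares IPD distributions (exact Mann-Whitney for small
samples, tie-corrected normal approximation otherwise).

**Nucleosome positioning signal (NPS).** On an aggregate WPS₁₂₀ track,
`NPS = Σ score(+135..+185) − Σ score(+10..+60)` — the +1-nucleosome window
minus the NFR window, both inclusive. `nps_by_bin()` ranks genes into
expression bins (1000 genes per bin, secondary global-expression sort key)
and correlates NPS with expression rank.

**Methylation and tissue deconvolution.** Per-cytosine calls are pooled
over target loci (coverage-weighted CpG fractions), and the sample profile
*m* over informative loci is decomposed against a reference atlas *A*
(loci × tissues) by constrained least squares:

```
min_X ‖A·X − m‖²   subject to   0 ≤ X_j ≤ 1,  Σ X_j ≤ 1
```

solved by projected-gradient descent with an exact projection onto the
feasible set. `1 − ΣX` is reported as the unknown (unreferenced-tissue)
fraction. Spike-in controls (unmethylated lambda, fully methylated pUC19)
quantify conversion efficiency and retention.

**Graft-derived cfDNA fraction.** In transplant recipients, donor-specific
A>T/T>A alleles (the only transversions immune to cytosine conversion) are
selected where the recipient is called reference; per-position allele
fractions are averaged, doubled when the donor is heterozygous, with a
normal-approximation 95% CI.

**Synthetic data.** `simulate_phased_fragments()` (dyad-jitter nucleosome
model), `simulate_methylation_mixture()` (binomial sampling over a Beta
reference atlas) and `simulate_allele_pileups()` generate fully seeded
inputs for every stage, so the complete pipeline is testable without
sequencing data.

## Worked example

```r
library(cfdnatools)

# nucleosome-phased cfDNA around a synthetic TSS (190-bp repeat, NFR, +1 dyad at +160)
frags <- simulate_phased_fragments(
  0, 4000, n_fragments = 30000, dyad_spacing = 190, dyad_jitter_sd = 5,
  nfr = c(1900, 2080), dyad_offset = 70, seed = 42
) |> filter_by_length("medium")

track <- raw_wps(frags, "chr1", 0, 4000, window = 120) |>
  normalize_by_count() |>
  subtract_running_mean()
peaks <- call_peaks(track)
interpeak_distances(peaks) |> dplyr::summarise(n = dplyr::n(), mean_ipd = mean(distance))
#>       n mean_ipd
#> 1    20     190.

agg <- aggregate_wps(frags, data.frame(chrom = "chr1", pos = 2000, strand = "+"),
                     window = 120, flank = 1000)
nps_score(agg)
#> [1] 7.991514
```

The 20 called peaks sit on the simulated 190-bp nucleosome grid (mean IPD
190 bp), and the positive NPS reflects the strong +1 nucleosome next to the
depleted NFR; an unphased library scores near zero.

```r
sim <- simulate_methylation_mixture(5, 300, depth = 100,
  true_coefficients = c(0.10, 0.55, 0.20, 0.10, 0.05),
  tissue_names = c("kidney", "monocytes", "liver", "neuron", "colon"), seed = 42)
deconvolve(sim$reference, sim$sample)
#> <tissue_composition> 300 loci, residual norm 0.7107, unknown fraction 0.00402
#>   tissue    coefficient
#> 1 monocytes      0.552
#> 2 liver          0.195
#> 3 neuron         0.112
#> 4 kidney         0.0911
#> 5 colon          0.0463

pu <- simulate_allele_pileups(0.097, "het", n_positions = 776, depth = 30, seed = 42)
estimate_graft_fraction(pu, donor_mode = "het")
#> <graft_fraction> 9.38% +/- 0.55% (95% CI), n = 776 positions, het donor (fractions doubled)
```

At sequencing depth 100 the five mixture coefficients are recovered to
within a few percent of truth, and the doubled heterozygous-donor estimate
brackets the simulated 9.7% graft fraction within its CI.

Each result type has an `autoplot()` method (aggregate footprints with the
NPS windows shaded, compositions as bar charts) plus `tidy()`/`glance()`
accessors, and `inst/cli/cfdnatools.R` exposes the same operations as
seeded, file-to-file subcommands.

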