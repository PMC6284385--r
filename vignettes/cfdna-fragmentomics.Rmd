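---
title: "Methods: cfDNA fragmentomics and shallow-WGS copy-number calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cfDNA fragmentomics and shallow-WGS copy-number calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csffrag)
```

`csffrag` analyzes shallow whole-genome sequencing (sWGS) of cell-free DNA
(cfDNA) along two complementary axes: the fragment-length distribution
(fragmentomics) and binned relative copy number. This vignette documents the
models, the tunable parameters and their defaults, the numerical choices,
and what the synthetic data generator does and does not emulate.

## 1. The fragment-length model

A cfDNA sample is modeled as a mixture of a **background** (non-tumor) and a
**tumor** component, mixed by the tumor fraction `tf`. On the integer bp
grid 50–700, each component density is a Gaussian mixture which, inside the
oscillation range (default 75–150 bp), is multiplied by
`1 + a * cos(2*pi*(x - phi)/p)`:

* Background: a sharp mono-nucleosomal mode (167 ± 12 bp), a broad
  **sub-nucleosomal shoulder** (110 ± 25 bp, weight 0.12), and a
  di-nucleosomal mode (320 ± 25 bp, weight 0.10); oscillation amplitude
  `a = 0.30`.
* Tumor: a 145 ± 12 bp mono-nucleosomal mode and a broader, heavier
  di-nucleosomal mode (300 ± 40 bp, weight 0.25), giving the relative
  220–320 bp enrichment seen in SCNA-positive samples; damped oscillation
  `a = 0.05`.

The shoulder deserves a note: real cfDNA profiles combine a *sharp* modal
peak at 167 bp with a long sub-150 bp tail on which the 10 bp ladder rides.
A single Gaussian cannot produce both — widening it enough to carry the
ladder flattens the peak until the empirical mode wanders by several bp.
The shoulder component resolves this while keeping every other piece of the
model minimal. The mechanism of the 220–320 bp enrichment is not modeled;
it is encoded phenomenologically as the elevated tumor di-nucleosomal
weight.

The oscillation has period 10.4 bp and phase 81 bp, placing the analytic
maxima near 82, 92, 102, 112, 123, 134, 145 bp — the canonical positions of
the nucleosomal ladder. The optional third mode at 133 bp (histone-variant
associated, seen in occasional samples) is off by default
(`variant_weight = 0`).

Lengths are drawn by inverse-CDF sampling on the integer grid, so output is
deterministic for a fixed seed across platforms, and the empirical
distribution converges to the analytic density (`length_density()`), which
doubles as the reference for analytic tests.

## 2. Genomic placement and the synthetic genome

The default genome is a desk-scale stand-in for the human autosomes: 22
chromosomes of 3 Mb (≈ 1:47 scale), tiled into 30 kb bins (2,200 bins
total). Per-bin GC is drawn once per genome build from Beta(41, 59)
(mean 0.41, sd ≈ 0.05, matching genome-wide 30 kb GC variability);
mappability is 1.0 except 2% dropout bins at 0.5; 1% of bins form a
blacklist of artifact-prone regions. Chromosome-level bin counts (100) stay
large enough for segmentation while keeping a full 13-sample cohort run
under a minute.

A fragment is tumor-derived with probability `tf`. Placement is binned:
background fragments land in bin *b* with probability proportional to
`map_b * (1 + s*(gc_b - mean(gc)))`, tumor fragments additionally carry
`copies_b / 2` from the copy-number profile. The expected count ratio of a
bin with `c` tumor copies to a neutral bin is therefore
`[(1-tf)*2 + tf*c] / 2`, e.g. 1.25 (log2R ≈ 0.32) for a 3-copy gain at
`tf = 0.5`. The default GC-bias slope is `s = 0.5`, a mild linear bias that
the correction step must remove.

Gene regions (`glioma_genes()`) rescale GRCh37 coordinates of a
glioblastoma panel (EGFR, PTEN, CDKN2A, ...) onto the synthetic
chromosomes, padded to ≥ 120 kb so each region spans several bins.

Per-sample fragment counts default to 2 × 10^5 — the 10-million-fragment
depth-matching convention scaled by the ≈ 1:47 genome — and cohorts derive
per-sample seeds from one global seed by counter-based splitting
(`seed + 104729 * i mod 2^31-1`), making cohort results independent of
generation order.

### What the generator does not emulate

No read-level simulation (no sequencing errors, duplicates, alignment
artifacts), no chromatin-context covariates beyond GC/mappability, no
subclonal mixtures, no plasma/urine biology beyond parameter presets, and
no mechanistic model of the 220–320 bp enrichment. Passing tests therefore
demonstrate the *pipeline's* correctness and the qualitative behavior of
the statistics under controlled conditions — not clinical performance on
patient data.

## 3. The 10 bp periodicity amplitude

For a size profile with height `h(x)` (fragments of length `x` over total
fragments; integer-bp resolution, never smoothed):

1. **Extrema.** `y` in 75–150 bp is a maximum iff `h(y)` is *strictly*
   largest within `[y-2, y+2]`; minima symmetric. Exact ties disqualify all
   tied positions — integer count data do tie, and the conservative rule is
   reproducible. Positions whose window leaves the profile range are
   ineligible.
2. **Clear peaks.** A sample qualifies for position averaging if its maxima
   contain a run of ≥ 5 consecutive positions spaced 8–13 bp apart. The run
   form (rather than demanding *every* spacing be comb-like) tolerates
   stray noise maxima in the weak 75–100 bp tail at shallow depth while
   still rejecting flat or tumor-dominated profiles.
3. **Averaging.** Positions pool across qualifying samples and cluster
   greedily within ±3 bp (under half the period, so neighboring teeth never
   merge); clusters supported by ≥ 50% of qualifying samples are averaged
   and rounded half-up to 1 bp.
4. **Amplitude.** `A = sum(h at consensus maxima) - sum(h at consensus
   minima)`, computed for *every* sample at the shared consensus positions
   (a per-sample variant exists but is non-canonical). `A` is scale-free in
   the counts.

At fixed positions `A` is linear in `tf`, hence strictly decreasing
whenever the tumor comb is damped; `analytic_amplitude()` verifies this on
the exact density, using the background density's extrema as the consensus
positions (the analytic counterpart of "samples with clear peaks").

## 4. Binned copy-number calling

* **Counting.** Each fragment goes to exactly one 30 kb bin by its start
  coordinate (half-open boundaries).
* **Correction.** Stratified median-ratio factors: GC strata of width 0.01
  and mappability strata of width 0.05; each stratum factor is its median
  count over the genome-wide median, renormalized to per-bin median 1;
  strata with < 5 bins fall back to the pooled median with a warning.
  Stratified medians were chosen over loess for determinism and freedom
  from smoothing parameters. Blacklisted bins are excluded throughout.
* **log2R.** `log2(corrected) - median(log2(corrected))` over usable bins —
  normalizing on the log scale makes the median log2R *exactly* zero for
  even bin counts too. Zero-count bins are flagged unusable, never −Inf.
* **CBS.** Recursive binary splitting at the max-|t| (pooled variance, arms
  ≥ 2 bins) with a permutation test (1,000 permutations, α = 0.01, seeded;
  early-stopped once significance is impossible). A constant segment
  cannot split (the 0/0 t-statistic is defined as 0).
* **HMM.** Three states with fixed means (−0.5, 0, +0.4), shared variance
  by method of moments on median-centered data (floored at 10^-4 to keep
  emissions proper on noiseless input), symmetric transition probability
  10^-3, uniform initial probabilities, Viterbi decoding; runs of equal
  state become segments with empirical means. Fixed means keep shallow-depth
  behavior deterministic; EM estimation is deliberately avoided.
* **Consensus.** Per bin, the mean of the CBS and HMM segment means — both
  segmentations must partition the same usable bins.
* **Gene calls.** Mean consensus log2R over a region's usable bins,
  thresholded at ±0.15 (echoed in the output); regions without usable bins
  are `no-data`. The thresholds imply a detection floor: a single-copy
  whole-chromosome gain reaches +0.15 only at `tf ≥ ~0.23` (loss at
  `~0.20`), which the detection tests respect.
* **Mean SCNA.** Mean |consensus log2R| over usable autosomal bins — an
  operationalization chosen because it is monotone in both event breadth
  and amplitude and scale-free; signed or segment-weighted alternatives
  were rejected as either cancel-prone or redundant.

## 5. Cohort association

`pearson_cor()` (product-moment r, two-sided p from the t distribution with
n−2 df — standard at cohort sizes near 13) relates the amplitude to the
mean SCNA. `scna_detected` comes from gene/region calls, not from
thresholding mean SCNA, matching how samples are grouped for fragmentation
comparisons. Degenerate cohorts (constant statistic, e.g. all tumor-free)
are reported gracefully rather than as r = 0. Metadata columns are carried
as opaque strings; no statistics are computed on them.

## 6. Problem sizes and determinism

Default test and reproduction scale: 13-sample cohorts at 2 × 10^5
fragments per sample; event-recovery checks use 10^6 fragments (where a
tf = 0.4 chromosome gain yields log2R ≈ 0.26 against per-segment noise
< 0.01); repeated-cohort properties use 100 seeded replicates. All
randomness flows from explicit integer seeds; the permutation test, the
simulator and down-sampling are reproducible bit for bit.

## 7. Known limitations

* The synthetic genome's 3 Mb chromosomes compress focal-event geometry;
  focal and whole-arm events differ only by a few bins.
* The amplitude's absolute scale depends on the shoulder weight and
  oscillation amplitudes; only its ordering across tumor fractions, not its
  absolute value, transfers to real data.
* The HMM's fixed state means assume near-diploid baselines; high-ploidy
  genomes would need different anchors.
* BAM input trusts upstream duplicate marking and proper-pair flags;
  fragment length is |TLEN| of read 1, so split or discordant pairs are
  dropped, not rescued.
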