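---
title: "Methods: cfDNA fragmentomics features and stacked classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cfDNA fragmentomics features and stacked classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Plasma cell-free DNA (cfDNA) is released mostly by apoptotic cells in
nucleosome-protected fragments with a ~167 bp mode. In a cancer patient a
fraction *f* of these fragments (the tumor fraction) derives from tumor
cells, and those fragments differ from the background in three measurable
ways that do not require deep sequencing or mutation calling:

* **Copy number (CNV).** Tumor genomes carry chromosomal gains and losses.
  A locus at tumor copy number *c* contributes cfDNA in proportion
  $(1-f) + f\,c/2$, so shallow whole-genome coverage in 1-Mb bins, expressed
  as a log2 ratio against a healthy baseline, shows segmental shifts of
  $\log_2(1 + f/2)$ for a single-copy gain and $\log_2(1 - f/2)$ for a
  single-copy loss.
* **Fragment size (FSD).** Tumor-derived fragments are, on average, shorter
  by tens of base pairs. Binning fragment lengths from 110 bp upward in
  twenty-four 5-bp bins on each chromosome arm, and z-scoring the counts
  within each sample, yields a size-distribution fingerprint
  (39 arms x 24 bins = 936 features with the default human arm set).
* **Nucleosome footprints (NF).** Chromatin that is open in the tumor's
  tissue of origin sheds fewer nucleosome-protected fragments at
  transcription-factor binding sites (TFBS). Composite, GC-corrected
  coverage in a +/-960 bp window around each site set is summarized by
  three numbers per set: central coverage (mean within +/-30 bp), average
  coverage (mean over the window), and the amplitude of the ~193 bp
  nucleosome periodicity, read from the discrete Fourier component nearest
  that period (index 10 of the 129-point window), scaled by 2/N.

The three feature blocks feed a two-tier stacked ensemble: per block, five
learner families (regularized logistic regression, two gradient-boosted
tree variants, random forest, feed-forward network) are grid-searched under
one shared, label-stratified 5-fold assignment; the five candidates with
the best pooled cross-validation AUC form the block ensemble (unweighted
mean of member probabilities); the final cancer score is the unweighted
mean of the three block scores, in [0, 1]. A decision threshold is
calibrated on training controls to target 95% specificity.

## Coordinate frames and conventions

All coordinates are 0-based, half-open (BED convention). Fragments are
assigned to bins and arms by their midpoint, so each fragment is counted
exactly once. The default human arm set is the 22 autosomes split at their
centromeres minus the p arms of the five acrocentric chromosomes
(13, 14, 15, 21, 22), which are essentially unsequenceable with short
reads: 22 x 2 - 5 = 39 arms exactly. The set ships as an editable
packaged table (`default_arm_table()`); the feature dimensionality
(39 x 24 = 936) is the load-bearing contract, membership is configuration.

The size-bin edges are twenty-four contiguous half-open 5-bp bins
[110, 115), ..., [225, 230). The within-sample z-score uses one mean and
one SD over all cells of the arm x size matrix (not per-arm statistics), so
the features describe the shape of the distribution, not sequencing depth;
the SD is the n-1 sample SD.

Depth is defined as total fragment bases divided by genome length —
fragments, not reads, are the unit throughout. Samples above the 5x
standardization target are Bernoulli-thinned at rate target/depth;
shallower samples are left untouched.

## Copy-number model

Per-bin depths are GC-corrected by dividing by a robust loess fit
(`family = "symmetric"`) of depth against bin GC, rescaled to preserve the
genome-wide mean; the robust family matters because CNV segments are
outliers with respect to the GC trend and a least-squares fit would absorb
part of the copy-number signal into the GC curve. The baseline is the
per-bin median of a GC-corrected healthy panel. Log2 ratios are
median-centered, which assumes a predominantly neutral genome.

Segmentation uses a four-state Gaussian HMM (loss, neutral, gain,
amplification) with a shared emission SD, a sticky self-transition (0.999)
and Viterbi decoding per chromosome. Two choices depart from a fixed-mean
textbook HMM and are what make shallow events callable:

* the emission SD is estimated from the data (median absolute deviation of
  successive kept-bin differences divided by sqrt(2)), floored at 0.01,
  rather than fixed at a scale appropriate for deep sequencing;
* the state means are scanned over a grid of candidate tumor fractions
  $f_c$ (loss $\log_2(1-f_c/2)$, gain $\log_2(1+f_c/2)$, amplification
  $\log_2(1+f_c)$), and the candidate whose Viterbi path attains the
  highest log-probability wins. A single-copy gain at $f = 0.1$ shifts
  log2 by only 0.07 — far below the canonical state mean of 0.25 — and is
  invisible without the scan.

Because a segment explained as a gain at $f_c$ is explained equally well as
an amplification at $f_c/2$, transitions into the amplification state are
down-weighted (relative entry weight 0.2), resolving the tie toward the
parsimonious single-copy interpretation.

The tumor-fraction estimate inverts the single-copy model per non-neutral
segment (gain: $f = 2(2^r - 1)$; loss: $f = 2(1 - 2^r)$, with *r* the
segment's median log2 ratio) and takes the bin-count-weighted median over
segments, clipped to [0, 1]; it is 0 when nothing is called. This is a
deliberately simplified, self-contained analogue of tumor-fraction callers
for shallow WGS: no subclonal states, no B-allele frequencies.

## Nucleosome-footprint details

The composite window is +/-960 bp at 15-bp steps (129 points) and the
amplitude targets the ~193-bp nucleosome repeat; both follow the
conventions of the site-anchored coverage framework this feature family
comes from, and both are configuration. "Central coverage" is read as the
mean over the +/-30 bp window rather than the single value at +30 bp; the
windowed mean is noise-robust and consistent with that framework. Profiles
are normalized to mean 1 over the window, so `average coverage` is exactly
1 by construction for every set — it is carried as a feature for interface
completeness and is dropped automatically (zero variance) wherever it
would be tested. Minus-strand sites are mirrored before accumulation.
Fragment-level GC weights (inverse of a smoothed observed-vs-expected GC
density ratio, clipped to [0.2, 5], mean-normalized) are available via
`fit_gc_model()`; the synthetic study leaves them off because bin-level
correction already removes the simulated bias where it matters (CNV), and
site-composite ratios are insensitive to smooth genome-wide bias.

## Stacked ensemble and threshold calibration

Fold assignment is stratified and shared verbatim across blocks, so block
scores are averageable per sample without leakage. Within a block,
candidates are ranked by pooled out-of-fold AUC; ties break by a fixed
family order, then grid order, making training bit-reproducible under a
master seed (all learner seeds derive from it; single-threaded fits). New
samples are scored by the unweighted mean of the k fold models of each
selected member — not by a full-data refit — so prediction scores are
exchangeable with the out-of-fold scores used downstream.

Threshold calibration needed two non-obvious decisions, both adopted after
their naive versions measurably under-covered on held-out controls:

1. **Nested calibration.** The ensemble's own out-of-fold scores are not
   honest for threshold purposes: the top-5 selection maximizes AUC on
   exactly those scores, compressing the control tail (controls that a
   candidate happened to score low made it more likely to be selected). The
   pipeline therefore re-runs the entire selection procedure k times with
   one fold held out and calibrates on the held-out scores, which are
   exchangeable with scores of genuinely new samples. In a direct
   experiment on the default synthetic study, fresh controls exceeded the
   maximum of the naive out-of-fold control scores about 17% of the time,
   versus the ~5% that exchangeability predicts.
2. **Add-one quantile.** With n training controls, the smallest cut whose
   empirical training specificity reaches the target sits just above the
   ceiling(target x n)-th order statistic, which in expectation covers only
   the m/(n+1) quantile (about 0.90 for n = 20 at target 0.95). The
   threshold therefore uses m = ceiling(target x (n+1)) — the add-one
   (conformal) order statistic — which guarantees the intended marginal
   specificity without distributional assumptions. For n = 10 controls the
   two rules coincide (both place the threshold just above the largest
   control score).

Calls are positive at `score >= threshold` (boundary inclusive).

## The synthetic cohort generator

The generator emulates exactly the signal structure the features consume,
on a miniature genome so that 5x-equivalent cohorts are desk-scale:

* **Genome.** Two chromosomes (50 Mb + 30 Mb), centromeres at the
  midpoints; 1-Mb bins; all four arms used. Dedicated test layouts (a
  14-Mb unit-test genome; a 170-Mb titration genome carrying 100 Mb of
  single-copy CNA split evenly between a gain and a loss) follow the same
  construction.
* **Lengths.** Healthy mixture 0.9 N(167, 10) + 0.1 N(320, 25), clipped to
  [60, 500] bp — the mono-/di-nucleosome structure the FSD features rely
  on, without claiming any empirical cohort's distribution. Tumor
  fragments shift the component means by -20 bp.
* **Copy number.** The default tumor genome carries one single-copy gain
  (chrA 5-20 Mb, copy 3) and one single-copy loss (chrB 18-28 Mb, copy 1);
  fragment density scales as $(1-f) + f\,c/2$, so an injected copy-3 locus
  at fraction f shows the closed-form depth ratio $1 + f/2$.
* **Nucleosome depletion.** Ten random TFBS site sets of 200 sites; the
  first three are "active": tumor-component fragments overlapping a site
  center +/-150 bp are thinned with probability 0.7. Depletion rides on the
  tumor component, so the footprint scales with f and vanishes at f = 0.
* **GC bias.** Fragment GC follows a smooth sinusoidal genome baseline
  (mean 0.45, amplitude 0.08, period 20 Mb) plus N(0, 0.04) noise;
  acceptance is logistic in GC, giving the GC-correction steps real signal
  to remove. The draw count is inflated by the estimated acceptance rate so
  realized depth still hits the nominal target within ~2%.
* **Cohorts.** Cancer tumor fractions draw from Uniform(0.05, 0.30) — the
  shallow-WGS-detectable range — with per-sample seeds derived from one
  master seed; a pseudo-stage (I-IV by f quartile bands) mirrors the
  stage-tumor-burden association of real cohorts.

What the generator does **not** emulate: sequence content (GC is an
annotation, not computed from bases), mappability artifacts, library
preparation chemistry, subclonal structure, inter-individual germline CNV,
or biological variation in the healthy length mixture. Passing tests
therefore demonstrate that the pipeline recovers the signals it models, at
realistic noise levels — not clinical performance on patient plasma.

## Problem sizes and runtimes

The default end-to-end study uses 20 cancer + 20 healthy training samples
and 10 + 10 held-out samples at 5x depth on the 80-Mb miniature genome
(~2.2 M fragments per sample), chosen so the full simulate-extract-train-
evaluate cycle completes in a few minutes on one core with ~1 GB of
memory; samples are streamed one at a time through feature extraction.
Unit tests run the same machinery on the 14-Mb genome at 0.3-2x. Parameter
recovery (tumor fraction at f = 0.10 within +/-0.03; gain log2 within
+/-0.03 of log2(1.2)) uses the titration genome at 1x, where a 50-bin
segment median has an MC error well inside those bands. The bootstrap AUC
interval uses B = 1000; the Jonckheere-Terpstra test switches to exact
enumeration at total n <= 12.

## Numerical and degenerate-input choices

* GC curves require >= 10 usable bins; loess predictions are floored at
  10% of mean depth before division.
* `fsd_zscore()` refuses constant matrices (zero SD); `log2_ratios()`
  refuses non-positive baseline bins.
* Welch t-tests skip features whose variance is zero in both groups (up to
  float noise), reporting them as skipped rather than producing NaN.
* The LoD-50 logistic floors f = 0 at 1e-4 before taking log10; under
  complete separation (diverging slope or a fitted-probability warning) it
  reports the interval between the largest fully-undetected and smallest
  fully-detected grid points, with f50 at the geometric midpoint.
* Jonckheere-Terpstra uses a tie-corrected variance and a 0.5 continuity
  correction in the normal approximation.
* Both Wilson and Clopper-Pearson intervals are provided; sensitivity,
  specificity and PPA default to Wilson.

## Known limitations

* The NF block cannot separate the lowest simulated tumor fractions from
  healthy counting noise (a depletion of f x 0.7 at f = 0.05 is below the
  per-set noise floor at 5x with 200 sites per set); healthy samples
  occasionally present moderately dipped central coverage and receive
  intermediate stacked scores. With only 20 training controls, any
  order-statistic threshold estimates the upper tail of that score
  distribution coarsely, so held-out specificity at the 95% target retains
  appreciable sampling variability across cohort draws even after nested
  calibration.
* The copy-number model is single-clone and integer-copy; subclonal
  fractions bias the estimate toward the clonal interpretation.
* The gain/amplification ambiguity is resolved by a prior (entry-weight)
  choice, not by data, whenever both interpretations fit equally well.
* The repeated-partition robustness evaluation re-tunes its threshold on
  each validation split; its specificity distribution reflects that
  protocol, not the nested-calibration protocol of the primary study.
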