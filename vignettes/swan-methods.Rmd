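---
title: "Subset-quantile within-array normalization: model, choices, limits"
author: "methylSWAN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subset-quantile within-array normalization: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylSWAN)
```

## The model

Dual-design methylation arrays measure, for each CpG probe, a methylated
intensity M and an unmethylated intensity U; the methylated fraction
β = M/(U + M) summarizes methylation in [0, 1] and
M-value = log2(M/U) is the logit-like scale preferred for testing. The two
probe chemistries on the platform produce systematically different
intensity and β distributions. Part of that difference is biology — type I
probes concentrate in CpG-dense regions — and part is a technical artifact:
type II β distributions are compressed toward 0.5.

The normalization rests on one assumption: **probes with the same number of
CpGs under the 50 bp probe body sample comparable biology, so their
intensity distributions should agree across designs**. Probes with one, two
and three body CpGs are the strata where both designs are well represented;
per stratum and design, N probes are drawn without replacement, with N the
minimum stratum size, giving a pool of 3N probes per design.

For each sample and each channel independently, the two pooled subsets are
sorted and each rank k is assigned the target
a_k = (x_I(k) + x_II(k))/2 — the standard quantile-averaging step restricted
to the subset. Subset probes receive a_k directly at their within-design
rank. Every other probe is mapped through the piecewise-linear interpolant
of the (x_sub, a) pairs of its own design. Outside the subset range the map
continues with unit slope: a probe d units above max(x_sub) gets
max(a) + d, and d units below min(x_sub) gets min(a) − d. Any normalized
intensity ≤ 0 is replaced by the median of that sample's negative-control
intensities for the channel; the count of such substitutions is recorded in
the returned object.

Downstream, two-group differential methylation uses a per-probe F statistic
on M-values: between-group mean square over the pooled within-group
variance, with the denominator replaced by the empirical-Bayes posterior
variance s̃² = (d₀s₀² + d·s²)/(d₀ + d) when shrinkage is on. The prior
(d₀, s₀²) is estimated by moment matching on log s²: under the scaled-F
sampling model the variance of log s² in excess of trigamma(d/2) equals
trigamma(d₀/2), which is inverted by a monotone Newton iteration; the mean
then identifies s₀². P-values use the F distribution with (1, d₀ + d)
degrees of freedom under shrinkage — the usual moderated-statistic
convention — and (1, d) without.

## Parameters that matter

* `seed` (subset draw) — the only stochastic element of normalization. One
  subset is shared across all samples of a dataset so that between-array
  comparisons use a common reference frame; `perArraySubset = TRUE`
  re-draws per array (sub-seeded deterministically) for sensitivity
  analysis.
* `eligibleCounts = 1:3` — the body-CpG strata defining the subset. Probes
  with 0 or more than 3 body CpGs are legal, are never subset candidates,
  and are always normalized by interpolation.
* `offset` in `getBeta()` (intensity units, default 0) — the plain ratio
  matches the definition above; entries with M + U = 0 are then undefined
  (returned as NA and excluded downstream). A conventional stabilizing
  offset such as 100 is available.
* `epsilon` in `getMvalues()` (intensity units, default 1) — guards
  log2(M/U) against zero intensities; the plain log-ratio is the
  epsilon → 0 limit.
* `gridStep = 0.001` and Silverman's rule-of-thumb bandwidth in
  `findPeaks()` — ΔP is the absolute offset between the two designs' density
  argmax on each side of β = 0.5. ΔP values are therefore internally
  consistent but tied to these density settings; with a one-sided β vector
  the missing peak is reported as NA rather than fabricated.
* `threshold = 0.01` in `filterProbes()` — a probe is dropped if its
  detection p exceeds the threshold in *any* sample; sex chromosomes
  (`chrX`/`chrY`, case-insensitive) are dropped by default because
  mixed-sex designs confound them.
* q-values are Benjamini–Hochberg: deterministic and parameter-free.

The detection background model is this package's own definition (the
platform vendor's is not public): per sample, total signal under absence of
target is Normal with mean = median(neg Meth) + median(neg Unmeth) and
sd = MAD(neg Meth) + MAD(neg Unmeth) (MADs scaled to normal sd). Summing
the two channels' medians and MADs is deliberately conservative — the sum
of MADs upper-bounds the sd of the summed background when channels are
dependent. At least 10 controls per channel are required.

## Numerical choices

* **Ties.** Within a design's subset, ranks are made unambiguous by a
  stable sort on (intensity, probe id). For interpolation, duplicated
  subset intensities are collapsed to a single knot whose target is the
  mean of their targets, keeping the interpolant a function and preserving
  within-design monotonicity.
* **Degenerate strata.** An empty subset stratum is an error naming the
  stratum; a single-knot map interpolates to its sole target inside the
  (degenerate) range.
* **All-equal variances.** If every s² is identical the prior df is
  infinite and every posterior variance equals the common value.
* **Constant probes.** A probe constant across all samples has F = 0 and
  p = 1 by convention.
* **Trigamma inversion.** Newton steps in inverse-trigamma space with
  closed-form guards for very small/large arguments; non-positive excess
  dispersion maps to d₀ = ∞.

## What the simulator emulates

`simulateManifest()`/`simulateDataset()` generate arrays with the premises
the pipeline is built on: a body-CpG-count distribution skewed so design I
has the higher mean; island membership increasingly likely with body-CpG
count; true β from an island-conditional three-component beta mixture
(bimodal overall — islands mostly unmethylated, non-islands mostly
methylated); per-probe total intensity log-normal with a design-specific
location (design I brighter); independent multiplicative log-normal
measurement noise per channel (sd 0.15 on the log scale); and the artifact:
the observed methylated fraction of a design-II probe is
0.5 + λ(β − 0.5), identity for design I. λ defaults to 0.8, a plausibility
choice — the platform literature describes the compression qualitatively,
not quantitatively — so all simulation-based properties are relative to λ,
and λ = 1 injects no artifact. Technical jitter is one multiplicative
factor per (array, design, channel) (sd 0.05 on the log scale), so the
relative offset between the designs varies from array to array — the
between-array component a within-array normalization can act on. Arrays in
a group share true β and differ in all technical draws, i.e. they are
technical replicates; group 2 adds a signed β shift of magnitude
`deltaBeta` (default 0.3, clipped to [0, 1]) to a random fraction
`piAffected` (default 0.05) of probes. Negative controls are drawn from
the same normal background model the detection p-values assume. All
randomness flows from one master seed through fixed per-component
sub-seeds.

Problem sizes used in the shipped checks, chosen to keep a full run in tens
of seconds while leaving all effects well resolved: 20,000-probe arrays for
the peak-offset, replicate and two-group studies (10 seeds each, 3v3
groups), 5,000 probes/tests for calibration checks, 10,000 variances for
prior recovery, and one 485,577 × 6 set demonstrating full-platform scale.

## What the simulation does *not* show

* **The artifact is reproducible across replicates here.** λ is a fixed
  parameter, so two technical replicates are distorted identically, and
  raw replicates agree about the artifact "for free". On this generator,
  normalization *lowers* replicate β correlation by a few 10⁻⁴ — its map
  is estimated per array and that estimation noise is the dominant
  between-replicate technical difference once the artifact itself is
  shared. On real arrays the probe-type difference varies substantially
  from array to array, which is precisely the regime where a within-array
  correction also improves between-array agreement; a 5% scale jitter
  deliberately does not reproduce that regime, and we report the measured
  agreement changes rather than force the expected direction.
* **Detection of the simulated group effects is near ceiling.** With
  Δβ = 0.3, 3v3 groups and the default noise, both the raw and the
  normalized pipeline recover ~99–100% of truth positives at q < 0.05, so
  the TP% comparison between pipelines is dominated by ties and single
  borderline loci. The ranking-based AUC comparison is the informative one
  at these settings (normalization wins consistently).
* No bisulfite-conversion failure, SNP-under-probe artifacts, batch/plate
  effects, color-channel crosstalk, or spatial effects are modeled, and
  Type I probes' two bead addresses are not tracked separately — the
  algorithm operates on summarized M/U signals only.

## Known limitations

* ΔP depends on density-estimation settings; compare ΔP values only within
  one choice of bandwidth rule and grid.
* The moderated test supports exactly two groups, matching its intended
  use; k-group designs, paired designs and continuous covariates are out
  of scope.
* Between-array normalization and dye-bias correction are distinct
  problems and are not attempted here.
* File exchange is plain TSV with documented schemas; the vendor's binary
  IDAT format is intentionally unsupported so the package stays
  self-contained.
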