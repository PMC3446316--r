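# methylSWAN

Within-array normalization and differential-methylation analysis for DNA
methylation BeadChips that mix two probe chemistries (Infinium I and II) on
one array.

## The problem

Dual-design methylation arrays interrogate ~485,000 CpGs with two probe
types. The two designs query biologically different parts of the genome
(type I probes sit in CpG-dense regions far more often), but they also
differ *technically*: type II probes produce compressed β-value
distributions (β = M/(U + M), the methylated fraction of the total signal),
with peaks pulled toward 0.5. Naive quantile normalization between the
probe types would erase the biology along with the artifact.

The subset-quantile within-array normalization implemented here exploits
the observation that probes with the **same number of CpGs in the 50 bp
probe body** have similar intensity distributions regardless of design:

1. Draw N probes per design from each body-CpG stratum (1, 2, 3 CpGs),
   where N is the minimum stratum size, giving 3N probes per design. For
   each sample and each channel (methylated, unmethylated, processed
   independently), sort each design's subset and assign every rank the mean
   of the two designs' intensities at that rank — the averaged quantiles
   *a₁ ≤ … ≤ a₃N*.
2. Map every remaining probe onto the averaged subset distribution by
   linear interpolation through the (x_sub, a) pairs; a probe beyond the
   subset range by a distance *d* is assigned max(a) + d (or min(a) − d
   below). Any result ≤ 0 is replaced by the median of the sample's
   negative-control intensities for that channel.

Around the normalizer the package provides the full evaluation pipeline:
β/M-value summaries, the ΔP peak-offset diagnostic (distance between the
unmethylated/methylated density peaks of the two designs), replicate
agreement (two-sample KS test, Pearson correlation), detection p-values
from a negative-control background model, probe filtering, a moderated
F-test for two-group differential methylation with empirical-Bayes variance
shrinkage (prior estimated by moment matching on log variances with
trigamma inversion; posterior s̃² = (d₀s₀² + d·s²)/(d₀ + d)),
Benjamini–Hochberg q-values, and ROC/true-positive evaluation against a
reference truth table. A seedable simulator generates dual-design arrays
with the compression artifact injected, so every stage is testable without
vendor data.

## Worked example

```r
library(methylSWAN)

cfg <- simulationConfig()               # 20,000 probes, 3v3 groups, lambda = 0.8
man <- simulateManifest(cfg, seed = 1)
sim <- simulateDataset(man, cfg, seed = 1)
sim$dataset
#> MethylArraySet: 20000 probes x 6 samples
#>   design I: 5600, design II: 14400; negative controls: 100 (Meth), 100 (Unmeth)
#>   samples: S01, S02, S03, S04, S05, S06

norm <- swanNormalize(sim$dataset, seed = 1)
rbind(raw  = unlist(deltaP(sim$dataset, sample = 1)[c("dPU", "dPM")]),
      swan = unlist(deltaP(norm,        sample = 1)[c("dPU", "dPM")]))
#>        dPU   dPM
#> raw  0.083 0.082
#> swan 0.002 0.004
```

The raw sample shows the injected design-II compression: its unmethylated
and methylated density peaks sit 0.083 and 0.082 β-units away from the
design-I peaks. After normalization both offsets collapse to a few grid
steps.

```r
detp <- detectionPValues(sim$dataset)   # background model from the controls
filt <- filterProbes(norm, detp)        # detection p > 0.01 in any sample; chrX/Y
res  <- dmpFinder(filt, sim$truth$groups)
head(res, 3)
#>      probe_id mean_m_group1 mean_m_group2 delta_beta        F            p            q
#> 1606 cg001710     -1.472769     -6.290910 -0.2542186 267.8204 1.447687e-15 2.739168e-11
#> 3688 cg003905      5.607939      1.009153 -0.3115743 229.5691 9.562852e-15 9.046936e-11
#> 2805 cg002975      2.220356      6.382206  0.1656035 211.1670 2.629594e-14 1.194299e-10

ev <- evaluateAgainstTruth(res, truthTable(sim$truth))
ev$auc
#> [1] 0.9998029
ev$tp_pct
#>   q_threshold tp_percent
#> 1        0.01   98.64078
#> 2        0.05   99.41748
#> 3        0.10  100.00000
#> 4        0.20  100.00000
```

The F statistics are moderated (variance shrinkage toward the common
prior), `delta_beta` is the group-2 minus group-1 β difference, and the
evaluation labels loci positive when the reference |Δβ| exceeds 0.25 and
negative below 0.05.

A shell entry point with `simulate` / `normalize` / `metrics` / `compare` /
`dmp` / `evaluate` subcommands lives at `inst/scripts/swan_cli.R`; every
run writes a `provenance.json` (parameters, seeds, input digests) beside
its outputs.

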