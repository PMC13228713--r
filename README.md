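# cartilageT2

Quantitative MRI analysis of knee articular cartilage around an acute
loading experiment, for imaging scientists and musculoskeletal
researchers: voxel-wise T2 relaxation mapping from multi-echo spin-echo
(MESE) series, laminar (superficial/deep) splitting of cartilage
regions, distance-transform thickness morphometry, and pre/post
group-comparison statistics — exercised entirely on synthetic phantoms
and simulated cohorts with known ground truth.

## The models at the core

**Relaxometry.** Spin-echo signal decays as
`S(TE) = PD · exp(−TE/T2)`. T2 and PD are fitted per voxel by
Levenberg–Marquardt from a log-linear start, with the first echo
excluded by default (stimulated-echo contamination). Fits outside the
1–500 ms bounds, or below a signal floor, are flagged invalid and
excluded from all downstream means.

**Laminar splitting.** Each cartilage voxel's in-plane Euclidean
distances to the articular (background-facing) boundary and the
bone–cartilage interface are compared; the voxel is superficial iff
`d_art ≤ d_bone`, making the laminar border equidistant between the two
surfaces.

**Thickness.** Local thickness `t(v) = d_art + d_bone + s` (s = pixel
size), averaged per region over 7 slices on an in-plane upsampled grid;
exact (`k·s`) on slabs.

**Statistics.** Per region × layer cell (including the whole-knee
composite, the unweighted mean over the six load-bearing regions), a
linear mixed model

```
value ~ group * time (+ covariates) + (1 | participant)
```

is fitted by REML; within-group changes (post − pre) and between-group
differences of changes are reported with 95% CIs and Sidak-adjusted
p-values (`p_adj = 1 − (1−p)^m`, default m = 3).

## Worked example

```r
library(cartilageT2)

## a noisy six-region knee phantom (SNR ~ 30), fitted and split
ph  <- generatePhantom(phantomSpec(dim = c(3, 64, 64), sigma = 25), seed = 42)
map <- fitMap(ph$series, ph$mask)          # first echo excluded
lam <- laminarSplit(ph$mask)
map
#> T2Map: grid 3 x 64 x 64, 1176 valid voxels
#>   T2 (valid): median 48.20 ms [31.71, 66.28]
head(regionLayerMeans(map, lam), 4)
#>         region       layer    value nVoxels
#> 1 medial_femur superficial 51.55049     129
#> 2 medial_femur        deep 38.96896      72
#> 3 medial_tibia superficial 52.59325     102
#> 4 medial_tibia        deep 39.87939      84
```

The superficial/deep estimates sit on the generating truth (52/39 ms
before loading) to within the noise of ~100-voxel means.

```r
## a simulated 16 + 16 cohort of whole-knee composite superficial T2
tab <- generateCohort(cohortSpec(means = compositeT2Means()), seed = 42)
fitGroupTimeModel(tab, "composite", "superficial")
#> T2ModelFit [composite/superficial]: groups healthy, at_risk
#>   sigma_b^2 = 71.13, sigma_e^2 = 3.236, Sidak m = 3
#>                    contrast    type estimate     se     lo     hi      pRaw
#>         healthy: post - pre  within  -3.9292 0.6360 -5.176 -2.683 6.495e-10
#>         at_risk: post - pre  within  -3.5647 0.6360 -4.811 -2.318 2.085e-08
#>  between: at_risk - healthy between   0.3645 0.8995 -1.398  2.127 6.853e-01
#>     pSidak m
#>  1.949e-09 3
#>  6.255e-08 3
#>  9.688e-01 3
```

Both groups shorten by roughly 4 ms after loading (the generating
changes are −3.89 and −3.80 ms) with no between-group difference —
the structure the cohort simulator encodes.

An end-to-end run (phantoms → maps → laminae → thickness → models) is
one call: `runPipeline(validateConfig(list(seed = 1)), "out/")`, or via
the CLI wrapper in `inst/cli/cartilage-pipeline.R`.

## Acceptance script

`scripts/acceptance.R` recomputes the package's parameter-recovery
result from scratch: it simulates 500 pre/post cohorts (16 per group,
random-intercept SD 8 ms, residual SD 2 ms) whose generating composite
superficial changes are −3.80 ms (at-risk) and −3.89 ms (healthy), fits
the mixed model to every cohort, and writes the mean within-group
change estimates to JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

| Area | Functions |
|---|---|
| synthetic data | `phantomSpec`, `generatePhantom`, `cohortSpec`, `generateCohort`, `signalModel` |
| relaxometry | `fitOptions`, `loglinearInit`, `fitVoxel`, `fitMap` |
| geometry | `boundarySets`, `laminarSplit`, `selectLoadbearingSlices`, `resampleMask`, `regionalThickness` |
| statistics | `regionLayerMeans`, `compositeMeasure`, `fitGroupTimeModel`, `modelContrasts`, `sidakAdjust` |
| pipeline & I/O | `validateConfig`, `runPipeline`, `analyzeMeasurements`, `read`/`writeNifti`, `read`/`writeEchoSeries`, `read`/`writeMask`, `read`/`writeMeasurementTable` |

See `vignettes/cartilage-t2-methods.Rmd` for the modelling choices,
default parameters and their rationale, and what the synthetic world
does and does not establish.
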