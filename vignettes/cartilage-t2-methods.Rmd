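---
title: "Methods: cartilage T2 relaxometry, laminar morphometry and pre/post mixed models"
author: "cartilageT2 authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cartilage T2 relaxometry, laminar morphometry and pre/post mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartilageT2)
```

# The problem this package addresses

Articular cartilage responds to mechanical load within minutes: water is
expressed from the matrix and the transverse relaxation time T2 of the
tissue shortens, most strongly in the superficial half of the cartilage,
where collagen is oriented parallel to the surface and free water is
most abundant. Quantifying that acute response around a standardized
loading bout — in healthy knees and in knees at risk of osteoarthritis —
requires a chain of image-analysis steps: voxel-wise T2 mapping from a
multi-echo spin-echo (MESE) acquisition, splitting each cartilage region
of interest into superficial and deep laminae, measuring cartilage
thickness, and comparing groups over time with a mixed-effects model.

`cartilageT2` implements that chain as reusable, tested components, and
pairs it with a synthetic-data module so that every stage can be
validated against known ground truth without any image download.

# The relaxometry model

Signal in a spin-echo train decays mono-exponentially,

$$S(TE) = PD \cdot e^{-TE/T2},$$

with proton density $PD$ the amplitude at $TE = 0$. `fitVoxel()`
minimizes $\sum_k (S_k - PD\,e^{-TE_k/T2})^2$ by Levenberg–Marquardt
from a log-linear warm start (`loglinearInit()`, OLS of $\ln S$ on
$TE$, which is exact on noiseless data). The first echo of a MESE train
is contaminated by stimulated echoes and is excluded by default
(`excludeFirst = TRUE`); the synthetic generator gives this rule a
measurable consequence by inflating echo 1 by a factor $\alpha \ge 1$,
so that fitting with exclusion recovers truth exactly while fitting
without it is measurably biased.

Numerical choices, all of them assumptions where the underlying
protocol is silent, are:

* **T2 bounds 1–500 ms.** Physiologic cartilage T2 is tens of
  milliseconds; the bounds only exist to catch degenerate fits.
  An estimate that ends on a bound is flagged not converged and the
  voxel is invalid.
* **Convergence** when the relative RSS change drops below `1e-10`, or
  after 200 iterations.
* **Unweighted least squares** — the model is a plain proportionality,
  and magnitude-MRI noise is approximately homoscedastic at the SNR
  simulated here.
* **Minimum-signal rule**: a voxel with any non-positive included echo,
  or mean included signal below `minSignal`, is returned invalid
  without fitting — never as an exception, so map fitting cannot abort
  mid-volume.
* Voxels affected by chemical shift are handled as an optional
  exclusion mask supplied to `fitMap()`, not detected automatically.

Invalid voxels carry `NA` sentinels in the `T2Map` and are excluded
from every downstream mean.

# Laminar splitting and thickness

For each cartilage region on each sagittal slice, `boundarySets()`
finds the voxels 4-adjacent (in-plane) to background — the articular
surface — and those 4-adjacent to bone. `laminarSplit()` computes each
cartilage voxel's minimum Euclidean distance to both sets (exact
distance transform, centre-to-centre, in mm) and labels the voxel
superficial iff $d_{art} \le d_{bone}$, which makes the laminar border
equidistant between the two interfaces. Decisions worth stating:

* **Distances are 2-D (in-plane).** Slices are 3 mm against 0.365 mm
  pixels; 3-D distances would be dominated by slice anisotropy, and the
  segmentation the workflow mirrors is slice-wise.
* **Ties go superficial.** Equidistance needs a deterministic rule; a
  single-voxel-thick sheet is therefore entirely superficial.
* **4-connectivity** for boundary detection: stricter boundaries that
  remain stable on thin structures.

Local thickness at a voxel is $t(v) = d_{art}(v) + d_{bone}(v) + s$
with $s$ the pixel size; on a slab $k$ voxels thick this is exactly
$k\,s$ for every voxel, which is why the rule was chosen — it needs no
surface meshing and has a closed-form oracle. Regional thickness is
the mean of $t(v)$ over the region's voxels on the selected slices
(7 slices for thickness, 3 for T2, both centred on a user-supplied
landmark slice; finding that landmark is deliberately out of scope).
The higher-resolution morphometry grid is emulated by nearest-neighbour
label resampling (`resampleMask()`) through the affine world mapping;
deformable registration is out of scope.

# The group-by-time model

`fitGroupTimeModel()` fits, by REML through `lme4`,

$$y_{it} = \beta_0 + \beta_g\,group_i + \beta_t\,time_t +
\beta_{gt}\,group_i{\times}time_t\ (+\ covariates) + b_i +
\varepsilon_{it}, \qquad b_i \sim N(0, \sigma_b^2),\ \varepsilon
\sim N(0, \sigma_e^2),$$

one model per region × layer cell (the whole-knee composite — the
unweighted mean of the six regional means, formed per participant and
timepoint by `compositeMeasure()` — is just another cell). Contrasts
are the per-group within change (post − pre adjusted means) and all
between-group differences of changes; in the 2-group case the latter
equals the interaction coefficient exactly, and for balanced complete
data the adjusted means equal raw cell means.

* **Confidence intervals and p-values** use the normal approximation
  (z), the common large-sample mixed-model default; with 16
  participants per group the simulated coverage of the 95% interval is
  within a point or two of nominal (verified by the parameter-recovery
  test).
* **Sidak family size** is configurable; the default counts the
  reported comparisons per model — 2 within changes + 1 between
  difference = 3 in the 2-group case, 6 in the 3-group variant — and
  the adjustment is $1 - (1-p)^m$.
* **Degenerate inputs**: a noiseless simulated table has zero residual
  variance, where REML machinery fails; the fit then falls back to OLS
  on the same fixed effects, which preserves the cell-mean arithmetic
  (with zero-width intervals). Convergence diagnostics are carried on
  the returned object (`@converged`) rather than thrown, so that
  worked examples on degenerate tables still return estimates.
* **Missing cells** are dropped row-wise (mixed models tolerate
  imbalance); a composite cell is missing whenever any of its six
  regions is.

# What the synthetic data emulates — and what it does not

`generatePhantom()` builds a knee-like phantom: a cartilage shell over
a bone disc (an annular arc), the minimal geometry with both boundary
types the laminar algorithm needs. Defaults state the simulated world:

* seven echo times 11.1, 22.2, …, 77.7 ms; 0.365 mm in-plane pixels,
  3 mm slices — a typical 3T knee MESE protocol;
* two-layer truth: superficial 52 ms, deep 39 ms before loading,
  physiologic values for adult knee cartilage;
* shell thickness 2.19 mm (six pixels), inside the tibiofemoral range;
* first-echo inflation $\alpha = 1.1$ — a visible but moderate
  stimulated-echo artifact (any $\alpha > 1$ exercises the exclusion
  rule; the exact contamination level of a real train is
  protocol-dependent and unreported);
* Rician noise, i.e. the magnitude of a complex Gaussian perturbation,
  with $\sigma = 25$ against $PD = 1000$ — first-echo SNR ≈ 30, a
  plausible 3T figure. Scanner noise levels for the motivating
  protocol are unpublished, so this is an assumption, stated here
  once. At zero true signal the expected magnitude is
  $\sigma\sqrt{\pi/2}$, which the test suite checks empirically.

`generateCohort()` inverts the statistical model: cell means per
group × time × region × layer (defaults: representative published group
means for healthy and at-risk adults; random-intercept SD 8 ms;
residual SD 2 ms), plus optional age/BMI covariates. The composite
cells are carried with their own means rather than recomputed from the
regional defaults, because a participant-level composite need not equal
the mean of group-level regional summaries.

A green test on these phantoms establishes that the *operators* are
correct — exact recovery in the noiseless limit, agreement with
brute-force oracles, unbiased parameter recovery at realistic noise.
It does not establish anything about real knees: the phantom has no
anatomy, no partial-volume mixing at curved interfaces, no B1 or
chemical-shift artifacts, no deformable motion between timepoints, and
its noise is spatially white. Those are exactly the places where real
data diverge from the stated world.

# Pipeline and interfaces

`runPipeline()` chains the stages — phantom simulation per participant
and timepoint, map fitting, laminar splitting, slice selection,
thickness on the upsampled grid, measurement table, composite, models —
behind a JSON configuration validated by `validateConfig()` (unknown
keys, missing seeds and even slice counts are all reported together).
All randomness funnels through one explicit seed; rerunning a
configuration reproduces byte-identical tables, and the run manifest
hashes every output. Volumes are NIfTI-1 with JSON sidecars (echo
times, label dictionaries), tables are plain CSV. A thin command-line
wrapper (`inst/cli/cartilage-pipeline.R`) exposes the stages as
subcommands; it adds no behaviour of its own.

# Known limitations

* Mono-exponential T2 only; multi-component decay and full
  stimulated-echo (EPG) modelling are out of scope by design.
* Thickness is a 2-D distance-sum rule; strongly curved or partial
  regions are measured slightly thin near arc ends (visible in the
  annulus oracle, which is asserted only to half a pixel).
* Registration between grids is rigid affine-metadata resampling.
* The degrees-of-freedom treatment is asymptotic (z); with very small
  cohorts a t-approximation would be preferable.
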