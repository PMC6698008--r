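---
title: "Quantifying microvessel density and tumour-stroma percentage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microvessel density and tumour-stroma percentage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvdmorph)
```

## The morphometric model

Microvessel density is treated here as an *area fraction*, not a count per
mm²: the percentage of analysed tumour-tissue pixels that belong to
chromogen-positive clusters at least 100 pixels in size. The pipeline has
four stages, each exposed as a function so intermediate results can be
inspected:

1. `rasterize_annotation()` — the analysed area is the union of the
   delineation polygons minus the union of the exclusion polygons
   (damaged/absent tissue). Polygons are filled under the even-odd rule and
   a pixel counts as inside when its *center* lies inside; coordinates are
   0-based with pixel `(r, c)` centred at `(c − 0.5, r − 0.5)`. The
   even-odd/pixel-center convention makes rasterized areas agree with the
   shoelace polygon area to within a perimeter-order discretization error,
   which the test suite checks on random star-convex polygons.
2. `classify_positive_pixels()` — by default an RGB rule
   (`R ≥ 60`, `B ≤ 120`, `R − B ≥ 30`, `R − G ≥ 10`). DAB brown carries a
   strong red excess over blue; haematoxylin (blue-purple) and eosin (pink)
   backgrounds fail the blue ceiling. The constants are calibrated on the
   package's synthetic slides such that every sub-rule keeps a margin of at
   least ~2.7 standard deviations of the default channel noise
   (`noise_sd = 8`; a channel *difference* then has sd ≈ 11.3). With
   tighter margins a few percent of true vessel pixels are lost at high
   vessel density, which is visible as a systematic negative bias of the
   estimator. For real scanner/stain combinations the constants are meant
   to be replaced wholesale via `stain_config()`. An alternative
   stain-deconvolution mode thresholds the projection of channel optical
   densities onto a unit DAB vector; since this plain projection does not
   remove haematoxylin cross-talk, its default threshold (0.6 OD) sits well
   above the counterstain's projected density (~0.33 OD).
3. `label_components()` — maximal connected clusters, 8-connected by
   default (the common particle-analysis convention; 4-connectivity is a
   flag). Labeling runs as a single two-pass union-find over the full
   raster in C++; because it is single-shot there is no tiling seam to
   merge and results are trivially invariant to image partitioning.
4. `filter_components()` / `compute_mvd()` — "minimal hundred positive
   pixels" is read as *retain clusters of ≥ 100 pixels*; a 99-pixel cluster
   is dropped, a 100-pixel cluster kept, and the test suite pins this
   boundary exactly. Removed clusters contribute to neither the numerator
   nor the component count, but all analysed tissue pixels — stained or not
   — stay in the denominator.

The physical pixel size (default 0.23 µm, a 20× whole-slide scan) is
carried through for provenance but does not enter the percent statistic.

## The stereology model

`generate_grid()` places a square lattice with spacing
`s = sqrt(mask_pixels / n_points)` and a uniformly random sub-cell offset —
systematic uniform random sampling — so the expected number of in-mask
points equals the requested grid size (400 by default, the 20×-objective
grid). Random offsets make the estimator literally unbiased for area
fractions, which the tests verify on a checkerboard and on generated
mosaics; a fixed-origin mode exists to reproduce a specific count.
`compute_tsp()` implements stromal hits over stromal-plus-epithelial hits;
points in lumen, mucus, necrosis or background ("other") are excluded from
both counts — the reading of the hits formula that keeps the denominator
informative. Whether the original operator software instead re-draws such
points is unknowable from the outside; excluding them changes nothing in
expectation, only the effective sample size. Point scoring is automatic
from a class-map raster (ground truth of a synthetic slide, or any supplied
segmentation) or manual via a scored table, preserving the original
operator workflow.

## The statistical layer

* Pearson chi-square **without** continuity correction. This is a
  deliberate choice: the published baseline-table p-values that the
  acceptance checks reproduce (e.g. counts 10/35 vs 5/4 giving p = 0.042)
  match the uncorrected statistic; Yates-corrected values do not.
* ROC dichotomization maximizes Youden's J over all midpoints between
  consecutive distinct marker values, ties broken toward the smallest
  cutoff, "high" meaning strictly greater. The outcome variable defaults to
  the recurrence indicator and the cutoff is found per stage (two cutoffs
  per marker) — both are parameters, since neither choice is externally
  fixed.
* DFS events default to recurrence, with death without recurrence treated
  as censoring; this composite is configurable for the same reason.
* Cox models use Breslow tie handling by default (the convention of the
  major commercial statistics package; Efron by flag). Monotone likelihood
  (perfect separation) and non-convergence raise explicit errors rather
  than returning runaway coefficients.
* Backward-stepwise Cox removes one covariate per step — the largest Wald
  p exceeding `p_out = 0.1` — with no re-entry, matching common "p-out"
  semantics; the 5-year horizon is implemented as administrative censoring
  at 60 months *before* fitting. An empty final model is a valid result.
* Normality is assessed by the Kolmogorov-Smirnov statistic with the
  Lilliefors correction, since the normal parameters are estimated from the
  sample.
* Two-sided tests at α = 0.05 throughout; no multiple-testing adjustment
  is applied anywhere, as none is part of the analysis being reproduced.

Standard machinery is delegated: `survival` for Cox/KM/log-rank, `stats`
for the classical tests, `nortest` for Lilliefors. The package's own code
is the morphometry, the stereology, the Youden scan, the stepwise driver
and the generators; tests cross-check the Youden scan against `pROC` and
the labeling against a pure-R flood fill, keeping implementation and oracle
separate.

## What the generators emulate — and what they do not

`generate_slide()` renders: a blocky epithelium/stroma mosaic (64-px
blocks, ~4% lumen blocks) in haematoxylin/eosin-like colours; vessel
objects as ellipses and lumen-bearing annuli with sinusoidally jittered
boundaries (real CD31 vessels are ring-like); DAB-brown vessel pixels; and
i.i.d. Gaussian channel noise clipped to [0, 255]. Exact ground truth is
kept as label maps and recomputed by brute-force recount whenever masks
change, so `truth$positive_fraction` is a pixel-exact statement about the
arrays, never a target that might have drifted.

The positive-area budget is hit deterministically: the first `n − 1` vessel
areas are drawn adaptively from the configured size range, the last
vessel's area is whatever remains of the budget (unconstrained by the
range), and placements that cannot realize at least the range minimum —
because of clipping at the tissue border or overlap with already-placed
vessels — are rejected and redrawn. Construction-time validation rejects
specs whose budget is unreachable: `(vessel_count − 1) · min_size` must not
exceed the target pixel count, and the target must stay below 85% of the
tissue area.

Not emulated: nuclei-level texture, scanner artefacts (blur, stitching,
illumination gradients), chromogen intensity gradients within a vessel, and
spatially correlated noise. Passing the recovery tests therefore shows the
pipeline is correct *given its colour model*; it does not validate the
default RGB constants against any particular real scanner, which is why
they are configuration, not claims.

`generate_cohort()` draws two stages (defaults 53 and 54 patients — the
study conditions), binary clinicopathological covariates at configurable
prevalences, stage-specific lognormal MVD (medians 5.6% and 11.1%),
normal TSP (means 43 and 49%), and six-core ordinal TMA scores aggregated
by `aggregate_tma_scores()`. Survival uses an exponential baseline
(closed-form inversion; a Weibull would add a shape parameter nothing here
needs) scaled by `exp(Σ β·x)`; β may load on any binary covariate or on the
latent `mvd_high`/`tsp_high` indicators (marker above its stage-specific
distribution median). Random censoring uses a per-subject exponential with
rate `hazard · r/(1 − r)`, which makes the probability that censoring
precedes the event *exactly* the configured `r` for every subject
regardless of covariates; an administrative cutoff (default 120 months)
applies on top. Real cohorts violate much of this — non-proportional
hazards, informative censoring, correlated covariates — so the recovery
tests certify the estimators under the model's own assumptions, nothing
stronger.

## Numerical choices and degenerate inputs

* Rasterization uses half-open vertical spans (`y1 ≤ yc < y2`) so a scanline
  through a shared vertex counts one crossing, and pixel centers exactly on
  an edge resolve consistently.
* An empty analysis mask (delineation fully excluded) is an error, not a
  zero — a slide with no analysable tissue has no MVD.
* `dichotomize_roc()` requires at least two distinct values and both
  outcome classes; direction ties between orientations resolve to
  "high-positive" within a 1e-12 tolerance (the two orientations' J values
  are exact negations, so floating noise would otherwise flip the choice).
* `cox_backward_stepwise()` retries the full model once with each single
  candidate dropped if the initial fit fails, recording the dropped
  covariate in the removal trace with a missing p-value.
* All generators are deterministic functions of their spec's seed; the
  pipeline driver derives one sub-seed per step from the global seed so
  reruns are byte-identical.

## Problem sizes

The validation suite exercises: twenty 2000×2000-px slides spanning 1–20%
target positive fraction (recovery within 0.5 pp of truth on every slide;
observed worst-case error is below 0.1 pp); 200 random grid offsets for the
stereology bias check against a 3-standard-error band of the 400-point
binomial; 100 random datasets for the Youden-vs-exhaustive-scan identity;
200 simulated cohorts of n = 300 with true HR = 2 and ~30% censoring for
Cox recovery and CI coverage; and 50 paired stage II/III cohorts
(n = 200 per stage, log HR ±1 on the latent high-MVD indicator) for the
qualitative opposite-direction pattern, recovered in well over 90% of
seeds. Unit tests run the same code on 320–500-px slides.

## Known limitations

* The default stain constants are calibrated to the synthetic colour
  model; real slides need their own constants (the supplementary-script
  constants of any given ImageJ workflow can be dropped into
  `stain_config()` directly).
* TIFF reading is plain raster only — no pyramidal whole-slide formats;
  tiles exported from a scanner viewer are the expected input.
* The survival simulator's exponential baseline cannot express
  time-varying effects; the stepwise driver fits only main effects.
* Automated epithelium/stroma segmentation from raw H&E colour is out of
  scope: point scoring is either ground-truth/segmentation-raster driven or
  manual.
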