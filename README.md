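# mvdmorph

Digital morphometry of microvessel density (MVD) on CD31-immunostained whole
tumour sections, point-grid stereology for tumour–stroma percentage (TSP),
and the cohort statistics used to relate both markers to disease-free
survival (DFS) in stage II/III colon cancer — together with synthetic-data
generators that make every stage of the pipeline testable against exact
ground truth.

## The problem and who this is for

Angiogenesis has no direct single-marker readout; microvessel density is its
standard surrogate. Classical "hotspot" vessel counting is
observer-dependent, so a whole-section, fully digital alternative is
attractive: delineate the tumour area, digitally exclude damaged regions,
classify chromogen-positive (DAB-brown) pixels, cluster them, discard
clusters too small to be vessels, and report the percent positive area.
This package is for pathology-image analysts and biostatisticians who want
that estimator — and the downstream survival modelling — as tested,
scriptable R functions rather than a one-off ImageJ macro.

## The statistics at the core

* **MVD** on an analysed tissue area `A` (delineation minus exclusions):

  `MVD% = 100 · Σ_{c : |c| ≥ 100} |c| / |A|`

  where `c` ranges over connected components (8-connected by default) of the
  chromogen-positive pixel mask and `|c|` is a component's pixel count.
  Sub-threshold positive pixels stay in the denominator but never enter the
  numerator. The positive-pixel rule (`R ≥ r_min`, `B ≤ b_max`,
  `R−B ≥ δ_rb`, `R−G ≥ δ_rg`, or a DAB optical-density threshold) is fully
  configurable.
* **TSP** by systematic uniform random sampling: a square lattice of ~400
  points with a random sub-cell offset; `TSP% = 100 · n_stroma /
  (n_stroma + n_epithelium)`, points in other tissue excluded from both
  counts.
* **Marker dichotomization** by ROC: the cutoff maximizing Youden's
  `J = sensitivity + specificity − 1` over all midpoints between observed
  values, with "high" meaning strictly greater than the cutoff.
* **Survival**: Kaplan–Meier curves with the two-sided log-rank test;
  Cox proportional hazards (Breslow ties) with `HR = exp(β̂)` and 95% CI
  `exp(β̂ ± 1.96·SE)`; backward-stepwise Cox for 5-year DFS (administrative
  censoring at 60 months, iterative removal of the largest Wald p > 0.1).
* **Baseline tables**: uncorrected Pearson chi-square for counts,
  pooled-variance t-tests for continuous variables, Mann–Whitney U,
  Lilliefors-corrected Kolmogorov–Smirnov normality, Spearman's rho.

Because the original patient-level data are not deposited, the package ships
generators: `generate_slide()` renders vessel objects of controlled total
area fraction on an epithelium/stroma mosaic with exact pixel bookkeeping,
and `generate_cohort()` simulates two-stage cohorts under a configurable
proportional-hazards model — so recovery of known truth is a test, not a
hope.

## Worked example

```r
library(mvdmorph)

spec  <- slide_spec(500, 500, target_positive_fraction = 0.05,
                    vessel_count = 20, vessel_size_range_px = c(150, 900),
                    excluded_fraction = 0.1, seed = 7)
slide <- generate_slide(spec)
slide
#> Synthetic slide 500 x 500 px: 19 vessels, positive fraction 0.0509,
#>   stroma fraction 0.583, 10.3% excluded

quantify_slide(as_annotated_slide(slide))
#> MVD: 5.076% (11381 positive px in 19 components / 224192 analysed px; min size 100 px)
```

The generator realized a 5.09% true positive fraction (the spec asks for 5%
± 0.5 pp); the morphometry pipeline, working only from the rendered image
and the polygon annotations, recovers 5.076% — within 0.03 pp of truth.

```r
mask <- slide$tissue_mask & !slide$excluded_mask
grid <- generate_grid(mask, n_points = 400, offset_seed = 7)
compute_tsp(classify_points(grid, class_map = slide$class_map))
#> TSP: 59.76% (199 stroma / 134 epithelium hits, 62 other excluded)

pearson_chi2(matrix(c(11, 4, 14, 25), 2, byrow = TRUE))
#> Pearson chi-square: X2 = 6.1064, df = 1, p = 0.01347
```

A survival round trip on a simulated stage III cohort with a protective
high-MVD effect (true log HR −1):

```r
co  <- generate_cohort(cohort_spec(n_stage2 = 0, n_stage3 = 200,
                                   true_log_hrs = c(mvd_high = -1),
                                   seed = 42))$cohort
cut <- dichotomize_roc(co$mvd_percent, co$dfs_event)
grp <- factor(ifelse(co$mvd_percent > cut$cutoff, "high", "low"),
              levels = c("low", "high"))
km_logrank(co$dfs_months, co$dfs_event, grp)
#> high vs low: HR 0.39 (95% CI 0.25-0.60), log-rank p = 9.225e-06 (n = 200, events = 97)
```

The protective direction (HR < 1) is recovered. A backward-stepwise Cox over
the MVD group plus three noise covariates retains only the MVD group
(HR 0.43, p = 0.001) and records the removal order of the rest.

There is also a thin command-line front-end:

```sh
Rscript inst/cli/mvdmorph.R simulate-slide --target-fraction 0.05 --seed 7 --out-dir out/
Rscript inst/cli/mvdmorph.R mvd --image out/slide01.tiff \
    --annotations out/slide01_annotations.geojson --out-dir out/
Rscript inst/cli/mvdmorph.R stats --table2x2 11,4,14,25 --out-dir out/
```

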