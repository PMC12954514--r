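# voroperf

Voronoi-based hierarchical scoring of 3D pulmonary perfusion maps, and its
validation against pulmonary function tests (PFTs).

## The problem

Perfusion imaging (SPECT, or CT-derived perfusion estimates) gives a spatially
resolved picture of pulmonary blood flow, while PFTs — DLCO, FEV1, FVC,
FEV1/FVC, as % of predicted — summarize lung function in single global
numbers. Connecting the two requires condensing a 3D perfusion map into one
interpretable score per patient, and that is hard: raw tracer units vary with
dose and acquisition, and the common per-lung percentile rescaling destroys
absolute quantitation, so plain whole-lung statistics correlate poorly with
function. `voroperf` implements a hierarchical, parcellation-based scoring
framework for exactly this task, aimed at researchers validating perfusion
maps (clinical or AI-generated) against spirometry and diffusion data.

## The method

Each lung (left/right labelled mask, co-registered with the perfusion volume
on an isotropic grid) is parcellated into **Voronoi subvolumes**: seed points
are placed by Poisson-disk (Bridson) sampling with minimum spacing *r* (in
voxel units), and every lung voxel is assigned to its nearest seed. Statistics
are then computed at up to three levels:

1. **intra-subvolume** — each subvolume's voxel values are summarized by one
   of: min, max, median, mean, CoV (population sd / median), 25th / 75th
   percentile, skewness (normalized third central moment), or
   histogram-mode / median;
2. **inter-subvolume** — the per-subvolume values within a lung (or the
   pooled lungs) are aggregated by CoV, mode/median, median, 25th / 75th
   percentile, skewness, or the defect-volume statistic

   P_N = 100 x Σᵢ wᵢ [vᵢ ≤ (N/100)·maxⱼ vⱼ] / Σᵢ wᵢ,

   the percentage of lung volume in subvolumes at or below N% of the maximum
   subvolume value (weights wᵢ = subvolume voxel counts);
3. **left-right** — the two per-lung values are merged by min, max, average,
   volume- or perfusion-weighted average, or selectors of the
   largest/smallest/most-/least-perfused lung.

Four processing scenarios cover the pathways with and without Voronoi
discretization and with lungs pooled or split (Full L+R, Full L/R,
Voronoi L+R, Voronoi L/R), on raw-valued or per-lung percentile-scaled maps.
Because the seeding is stochastic, Voronoi scores are averaged over
independent seed realizations. A brute-force search over (scenario x radius x
intra x inter(x N) x left-right x map kind) then ranks every combination by
the magnitude of its Spearman correlation with each PFT measure, and the
top-ranked scores are validated as predictors of normal vs abnormal lung
function (abnormal if DLCO < 60, FEV1 < 70, or FEV1/FVC < 70) using
leave-one-out logistic regression with an exhaustive best-subset covariate
search and VIF collinearity diagnostics (full, and cross-group across PFT
measures).

Because clinical perfusion cohorts are rarely shareable, the package includes
a fully synthetic cohort generator — jittered ellipsoid lung masks, smooth
positive perfusion fields with insertable hypoperfused defects, and PFT
values coupled (with noise) to defect burden — so the whole protocol runs
and is tested without any external data.

## Worked example

```r
library(voroperf)

cohort <- makeCohort(cohortConfig(nCases = 12, masterSeed = 7))
rc     <- runConfig("coarse", baseSeed = 7, topK = 3)
scores <- scoreCohort(cohort$cases, rc)     # 12 cases x 41000 metric specs
search <- searchCorrelations(scores, cohort$pft, topK = 3)
search$best[, c("id", "rho", "p", "stars", "n")]
```

```
                                                     id    rho        p stars  n
DLCO           VORONOI_LR_SPLIT|10|P25|MEDIAN|-|AVG|raw  0.973 5.14e-07   *** 11
FEV1     FULL_LR_SPLIT|-|-|P_N|25|PERF_WEIGHTED_AVG|raw -0.972 1.29e-07   *** 12
FVC       VORONOI_LR_SPLIT|10|P75|P_N|80|MAX|percentile  0.909 4.19e-05   *** 12
FEV1_FVC   VORONOI_LR_SPLIT|10|MAX|P_N|65|MOST_PERF|raw  0.928 1.34e-05   *** 12
```

Each row is the best-correlated metric combination for one PFT measure; the
id encodes `scenario|r|intra|inter|N|LR|kind`. The first row reads: split the
lungs, parcellate at seed spacing r = 10, take the 25th percentile within
each subvolume, the median across subvolumes, and average the two lungs —
applied to the raw-valued map, Spearman rho = 0.973 against DLCO over the 11
cases with DLCO recorded (negative rho means the score rises as function
falls, typical for defect-volume metrics).

```r
cls <- classifyCohort(scores, cohort$pft, rc)
cls$model
```

```
LOOCV logistic model: 11 cases, 1 covariates
  AUC 1.000  F1 1.000  accuracy 1.000
  confusion: TP 6 FP 0 TN 5 FN 0
  FEV1_FVC_top2: -139.403 +/- 6.461
  bias: -27.557 +/- 13.347
```

The best-subset search picked a single covariate (the second-ranked
FEV1/FVC metric) that separates normal from abnormal function perfectly on
this small synthetic cohort; coefficients are mean ± sd over the
leave-one-out fits, on the standardized-covariate scale. Geometry primitives
are exposed directly as well:

```r
m <- cohort$cases[[1]]$mask
s <- sampleSeedsBridson(m, lungLabel = 1, radius = 12, rngSeed = 1)
assignVoronoi(m, 1, s)
#> Partition: 5 subvolumes over 12034 voxels (r = 12, realization 1, lung 1)
```

A command-line front end (`inst/cli/voroperf.R`) wraps the same functions as
`simulate | score | search | classify` subcommands with `--seed`, `--out`,
`--preset coarse|full` and a YAML config override.

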