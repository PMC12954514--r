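---
title: "Hierarchical Voronoi scoring of pulmonary perfusion maps: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Voronoi scoring of pulmonary perfusion maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scoring model

`voroperf` condenses a 3D pulmonary perfusion map into one global score per
patient and asks which way of doing so tracks pulmonary function tests (PFTs)
best. The scoring pipeline has three levels, applied per *processing
scenario*:

- **Parcellation.** Each lung (left = 1, right = 2 in the mask) is
  discretized into Voronoi subvolumes around Poisson-disk seeds with minimum
  spacing $r$. Bridson's algorithm draws the first point uniformly from lung
  voxels, then proposes up to `kAttempts` candidates in the spherical annulus
  $[r, 2r)$ around each active point, rejecting candidates whose containing
  voxel lies outside the lung or that fall within $r$ of an existing seed.
  Every lung voxel is then labelled with its nearest seed (Euclidean distance
  in voxel units; ties go to the lowest seed index, which makes the labelling
  deterministic and order-stable).
- **Intra-subvolume statistics** summarize the voxels of one subvolume:
  min, max, median, mean, CoV, 25th/75th percentile, skewness, and
  histogram-mode/median. CoV is deliberately the population standard
  deviation divided by the *median* — subvolumes are complete enumerations of
  their voxels, not samples, and the median keeps the ratio stable on skewed
  tracer distributions.
- **Inter-subvolume statistics** aggregate the per-subvolume values within a
  lung (or the pooled lungs): the same descriptive statistics, unweighted,
  plus the defect-volume statistic
  $$P_N = 100 \cdot \frac{\sum_i w_i\,[v_i \le (N/100)\max_j v_j]}
  {\sum_i w_i},$$
  with $w_i$ the subvolume voxel counts — the percentage of lung volume whose
  regional perfusion sits at or below $N\%$ of the best-perfused subvolume.
  The comparison is $\le$ ("at or below"), and the reference maximum is taken
  within the unit being summarized: per lung when lungs are split, pooled
  when they are analysed together.
- **Left-right combination** merges the two per-lung values: min, max,
  average, volume-weighted or perfusion-weighted average, or selection of the
  largest/smallest lung by volume or the most/least perfused lung. Ties on
  volume or perfusion select the left lung. The selectors matter for
  unilateral disease, where averaging the lungs equally would dilute the
  affected side.

Four scenarios route the data through these levels: *Full L+R* (no
parcellation, inter statistics on the pooled voxels, each voxel its own
subvalue with weight 1), *Full L/R* (per-lung inter statistics, then
left-right), *Voronoi L+R* (intra then inter on the pooled subvolumes), and
*Voronoi L/R* (the full three-level path). Every combination is evaluated on
both the raw-valued map and its per-lung percentile rescaling.

Because the seeding is stochastic, Voronoi scores are averaged over
`nRealizations` independent discretizations of the same radius — the
averaging applies to the final global score, not to intermediate levels, and
an undefined statistic (e.g. a zero median in a ratio) in any realization
makes the whole score undefined for that case. The search then ranks every
metric combination by $|\rho|$ (Spearman) against each PFT measure, with
two-sided p-values from the $t$ approximation; p-values are descriptive star
annotations only, with no multiple-testing correction, since the search is a
screening step rather than a hypothesis test.

# Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `isoMm` | 2.0 | mm | working isotropic spacing; between the in-plane (6 mm) and slice (2 mm) resolutions typical of reconstructed perfusion SPECT |
| `radii` | 10..90 (step 1 full / 10 coarse) | voxels | below ~10 subvolumes approach single voxels, above the lung diameter they approach whole lungs; both extremes make the statistics degenerate |
| `nGrid` | 5..95 (step 0.1 full / 5 coarse) | % | $P_N$ threshold sweep; the step is a resolution choice, not a model quantity |
| `nRealizations` | 5 full / 2 coarse | — | stabilizes the stochastic parcellation |
| `kAttempts` | 30 | — | Bridson's canonical candidate budget |
| `topK` | 5 | — | ranked metrics retained per PFT measure for classification |
| thresholds | 60/70/70 | % / % / ratio | abnormal if DLCO < 60, FEV1 < 70, or FEV1/FVC < 70 (strict inequalities); all three must be met for "normal" |

$r$ is interpreted in isotropic-voxel units (the limit "as $r \to 1$,
subvolumes approach single voxels" only makes sense in voxel units), so the
physical subvolume scale depends on `isoMm`.

# Numerical choices

- **Quantiles** use linear interpolation between order statistics (the
  common "type 7" convention). **Histogram mode** uses 64 fixed equal-width
  bins over $[\min, \max]$ (a single bin when the data are constant; count
  ties go to the lowest bin).
- **Percentile maps** assign each lung voxel its average rank divided by the
  lung voxel count, giving values in $(0, 1]$; ties share their average rank,
  so a constant lung maps to $(n+1)/(2n)$. This makes the map invariant under
  any strictly increasing transform of the raw intensities, which is the
  property the percentile representation exists to provide. (Mapping the
  minimum to 0 instead would be an equally defensible convention; the
  average-rank form avoids zero medians in downstream ratios.)
- **Caching.** The score-matrix sweep computes intra-subvolume values once
  per (case, radius, realization) and reuses them across the inter/left-right
  sweeps. All statistic kernels are shared, compiled routines, so the cached
  sweep is bit-identical to evaluating `globalScore()` spec by spec — a
  tested contract, not an aspiration.
- **Determinism.** Geometry sampling uses a self-contained Mersenne-Twister
  stream seeded per (case, radius, realization, lung), so results do not
  depend on R's RNG state and reruns are bit-identical; the synthetic
  generator spawns per-case substreams (`masterSeed + i`) so cohorts extend
  without reshuffling existing cases.
- **Logistic fits** are unpenalized maximum likelihood (Newton/IRLS, warm
  started from the full-data fit, which cannot change the optimum). On
  separable folds the coefficients diverge; iteration stops once every fitted
  probability is saturated, mirroring `glm`'s behaviour of returning the
  diverged fit. A tiny ridge (1e-8) is the fallback for genuine numerical
  failure (singular systems) and its use is disclosed in the model report.
  Covariates are z-scored on each training fold — the heterogeneous scales of
  the metric space make unstandardized coefficients meaningless — and the
  classification threshold for F1/accuracy/confusion is 0.5.
- **Missing DLCO.** Cases without DLCO cannot be assessed against the full
  abnormality rule and are excluded from classification (correlation uses
  pairwise deletion instead, so DLCO rankings simply use fewer cases).
  FVC is excluded from the classification candidate pool: it is dominated by
  body size and consistently the weakest-correlated measure.

# What the synthetic cohort emulates — and what it does not

`makeCohort()` generates jittered two-ellipsoid lung masks, smooth positive
perfusion fields (exponentiated blurred Gaussian noise, median about 1,
log-sd 0.25), spherical hypoperfused defects whose intensities are
*multiplied* by 0.25 (multiplying rather than replacing keeps percentile maps
informative inside defects), and PFT values that decrease linearly in the
volume-weighted total defect fraction with Gaussian noise, truncated at zero.
Left and right lungs draw independent defect fractions (uniform on
$[0, 0.5]$) so the left-right operators are exercised asymmetrically, and
3/36 of cases lose their DLCO value, matching the missingness structure of a
typical clinical cohort. The default noise levels put the generator-level
defect-to-FEV1 Spearman magnitude near 0.9, and the intercept/slope choices
make roughly a third of cases abnormal under the 60/70/70 rule — checked by
generator-level tests before any pipeline code runs, so generator bugs and
pipeline bugs stay separable.

What it does **not** emulate: airway/vascular anatomy, SPECT physics
(collimator blur, attenuation, Poisson counting noise), registration error,
or lobar structure. Passing the synthetic-recovery tests therefore shows the
*procedures* are correct and that the pipeline recovers a known
perfusion-function coupling; it does not certify performance numbers on
clinical data, whose defect morphology and noise are richer.

# Design choices where the design was genuinely open

- The N grid for $P_N$ has no prescribed step; 0.1 percentage points at full
  fidelity (5 at the coarse preset) resolves the threshold finely without
  exploding the search.
- Candidate rejection in the masked Bridson sampler tests the *containing
  voxel* of the continuous candidate (round to nearest index), and annulus
  radii are drawn volume-uniform on $[r, 2r)$; neither choice affects the
  spacing guarantee, only the exact point process.
- Perfusion totals used by the perfusion-weighted average and the
  most/least-perfused selectors are sums of in-mask voxel values of *the map
  being scored* (raw totals for raw specs, percentile totals for percentile
  specs).
- The best-subset search evaluates every non-empty subset of the candidate
  pool (capped at $2^{15}-1$ evaluations) by LOOCV AUC, with ties resolved by
  higher F1, then fewer covariates, then the lexicographic order of the
  sorted covariate ids.

# Problem sizes used by the test suite

The regression suite exercises the full protocol at the coarse preset
(radius step 10, N step 5, two seed realizations) on synthetic cohorts of
30 cases (64³ voxels at 2 mm): ten master seeds for the correlation-recovery
checks and one for the best-subset classification, plus an 8-case cohort for
the bit-reproducibility check. Oracle tests (exhaustive nearest-seed scans,
brute-force statistics, per-fold glm refits) run on instances up to 32³
voxels, 50 seeds, and multisets up to 1000 values. These sizes were chosen so
the whole suite doubles as a fast regression harness; the method itself has
no intrinsic size limit beyond memory.

# Known limitations

- **Selection optimism.** The best metric combination is selected and
  evaluated on the same LOOCV protocol (as is common for small clinical
  cohorts); reported AUCs are optimistic relative to a nested validation.
  On the synthetic cohorts the signal is strong enough that this is moot, but
  users applying the pipeline to real data should treat the search as
  screening, not inference.
- **LOOCV null pessimism.** Per-fold-refit LOOCV is *pessimistically* biased
  under the null: with an uninformative covariate, the training-fold
  intercept anti-correlates with the held-out label and the null mean AUC
  sits well below 0.5 (about 0.28 at n = 40, confirmed against an
  independent per-fold glm oracle). AUCs near 0.5 from this protocol
  therefore do not mean "chance"; they already indicate weak signal.
- Voxelized Voronoi labels, not exact continuous cell geometry; only the
  labelling is needed downstream.
- The undefined-value policy (any undefined statistic poisons the metric
  combination for that case, and ranking drops combinations undefined for
  any case) is conservative; on percentile maps, where medians cannot be
  zero, it never triggers.
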