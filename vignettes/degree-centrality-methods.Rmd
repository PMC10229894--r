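---
title: "Degree centrality, nested RFE-SVM classification, and the synthetic cohort model"
author: "restDC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree centrality, nested RFE-SVM classification, and the synthetic cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restDC)
```

## The statistic

Degree centrality (DC) summarizes how strongly each node of the
resting-state connectivity graph is coupled to the rest of the brain.
For node $i$ with time course $x_i$,

$$\mathrm{DC}(i) \;=\; \sum_{j \neq i} w(r_{ij}) \,\mathbf{1}[\,r_{ij} > \theta\,],$$

where $r_{ij}$ is the Pearson correlation of the two nodes' BOLD time
courses, $\theta = 0.2$ is a strict positive threshold that removes weak
noise-driven edges, and the default weight is the Fisher transform
$w(r) = \operatorname{atanh}(r)$, which variance-stabilizes correlation
estimates before summation. Only positive edges count: negative
resting-state couplings have a contested interpretation after global
signal regression and are excluded by design. Each subject's map is then
divided by its whole-brain (in-mask) mean, so maps are dimensionless
with mean 1 and inter-individual scaling differences cancel.

Two computational paths produce region features:

* **voxel path** — `voxelwiseDC()` computes voxel-level DC blockwise
  (the voxel-by-voxel correlation matrix is never materialized; results
  are identical for any block size to $10^{-10}$), `normalizeDC()`
  rescales, and `parcelAverage()` takes per-region means over an integer
  label volume;
* **ROI path** — `roiDC()` applies the same edge rule directly to the
  region-by-region correlation matrix of atlas-averaged series. This is
  the fast path used by the simulations; the test suite checks that the
  two paths agree in the *sign* of planted group effects.

Three edge-weight conventions are provided because published DC analyses
are often ambiguous about whether the statistic is a count or a sum:
`weighted_z` (default: sum of Fisher z over suprathreshold edges — the
literal reading of "threshold, then z-transform, then aggregate"),
`weighted_r`, and `binary`. Correlations are clipped at
$|r| = 1 - 10^{-6}$ before `atanh` so duplicated series produce a large
but bounded weight instead of infinity.

One normalization ambiguity was decided in favor of the literal
operation: "divide by the whole-brain mean" is implemented as division
(`normalizeDC()`), not as a subtract-mean/divide-SD z-map; the latter
changes the null distribution of parcel averages and is not what the
words say.

## Temporal preprocessing

The package implements the *temporal* stages that act on series already
in a common space (spatial registration is out of scope): initial-volume
dropping (default 10, for scanner equilibration), Friston-24 motion
expansion $[R_t, R_{t-1}, R_t^2, R_{t-1}^2]$ with the first lagged row
set to 0 (a convention; the data give no value for the pre-first
volume), nuisance regression (OLS residuals against confounds plus an
intercept; collinear columns are dropped with a warning), per-channel
linear detrending, and band-pass filtering.

The band-pass (default 0.01–0.08 Hz) is an **ideal DFT mask**: bins with
$f_{\mathrm{low}} \le f \le f_{\mathrm{high}}$ (inclusive on both edges)
are kept, everything else — including the 0 Hz bin whenever
$f_{\mathrm{low}} > 0$ — is zeroed. Compared to an IIR filter this has
exactly testable bin behavior (an in-band sinusoid on a DFT bin is
reproduced to $10^{-8}$; an out-of-band one is annihilated), no edge
transients to tune, and is idempotent. The default stage order is
drop → confound regression → detrend → band-pass, with smoothing (off by
default in synthetic runs) before confound regression when enabled;
`preprocessSeries()` records the stages actually applied in an
attribute.

Gaussian smoothing (`smoothGaussian()`, FWHM in mm,
$\sigma = \mathrm{FWHM} / 2\sqrt{2\ln 2}$) supports isotropic voxels
only and renormalizes at the volume edges, so constants are exactly
preserved.

## Classification: two-stage selection inside nested LOOCV

Subjects are labeled control/expertise with expertise coded $+1$, so a
positive SVM weight always means *higher DC in the expertise group*.

Within each outer leave-one-out fold (`nestedEvaluate()`, mode
`"nested"`):

1. **t filter** — pooled-variance two-sample t-test per region on the
   training subjects only; keep $p < 0.05$ (uncorrected). Degenerate
   regions with zero pooled variance get $p = 1$ (equal means) or
   $p = 0$ (unequal). If nothing passes, the single smallest-$p$ region
   is kept so the fold can still emit a prediction.
2. **contribution-based RFE** — for the active set $S$ with inner-LOOCV
   accuracy $\mathrm{acc}(S)$, each feature's contribution is
   $\mathrm{acc}(S) - \mathrm{acc}(S \setminus \{f\})$; all features
   with contribution $\le 0$ are removed at once. When every feature
   contributes, the single smallest contributor goes (ties: the larger
   original column index first); when none does and the rule would empty
   the set, the largest contributor (ties: smallest index) is kept. The
   loop records every iteration down to one feature; the chosen subset
   maximizes recorded accuracy with ties broken toward the smaller set,
   then the earlier iteration. This differs deliberately from classic
   weight-ranked RFE (|w|-ranking is available via the recorded traces
   but is not the default) — the elimination criterion here is the
   feature's measured effect on accuracy, not its weight.
3. **final model** — a linear soft-margin SVM (hinge loss, $C = 1$ by
   default; exposed) trained on the chosen subset, features standardized
   by training-fold mean/SD (SVMs are scale-sensitive and DC ranges
   differ across regions), scores the held-out subject.

The SVM dual is solved by a small SMO implementation (maximal violating
pair selection, tolerance $10^{-4}$, alphas snapped to the box to avoid
stuck pairs); the test suite cross-checks weights, bias and predictions
against libsvm via e1071 on random problems. Inner leave-one-out
accuracy re-standardizes within every inner fold, so the held-out
subject of any fold never touches standardization, filtering or
elimination — a property asserted by a test that corrupts a held-out
subject's features and verifies its fold's selection is unchanged.

Metrics follow the standard conventions: accuracy, sensitivity
(expertise recall) and specificity as percentages rounded half-up to two
decimals; AUC by pair counting with ties worth $1/2$ (equal to the
trapezoidal area under the empirical ROC staircase), reported to four
decimals.

A `"pooled"` mode runs selection once on all subjects and
cross-validates only the SVM. It mirrors the common practice of
reporting a single consensus region list, but it leaks the held-out
subject into selection and is therefore labeled *optimistically biased*
in its output; the test suite demonstrates the bias on null data. The
descriptive region/weight table reported alongside nested results comes
from this pooled fit and is labeled descriptive, not inferential.

## Group and brain-behavior statistics

Behavioral group comparisons use a tie-aware Mann–Whitney U test: exact
by enumeration of all group assignments of the pooled values when the
combined sample size is at most 12 (enumeration cost grows as
$\binom{n}{n_x}$; 12 keeps it trivial), otherwise a normal approximation
with tie-corrected variance and continuity correction. Per-ROI
brain–behavior association is a Pearson correlation within the named
group with two-sided $t$-based p-values, adjusted across ROIs by
Benjamini–Hochberg separately for each behavioral measure (the
correction family is all ROIs for one measure in one group — the
natural family for "which regions track this score"). "Correlating the
averaged DC with behavior" is only meaningful at the region level, so
the analysis is implemented there.

## The synthetic cohort model

Scanner data for expertise cohorts are effectively never deposited, so
the generator is the package's test bed, and its defaults *are* the
emulated study conditions: 22 subjects per group, 190 volumes at
TR = 2 s (of which the first 10 are dropped downstream), a 246-region
atlas, and behavioral targets of 0.80 ± 0.04 vs 0.53 ± 0.04 for the
expertise score (fraction correct), 2.6 ± 0.4 s vs 3.7 ± 0.7 s for its
response time, and 56.95 ± 5.23 vs 58.68 ± 5.31 for the face-memory
control task.

Each group's ROI process is a stationary multivariate AR(1),
$x_t = \phi\, x_{t-1} + \varepsilon_t$ with
$\varepsilon_t \sim N(0, \Sigma_g)$ and $\phi = 0.4$, started from the
stationary distribution so the lag-0 correlation equals the innovation
correlation at every time point (the covariance inflates uniformly by
$1/(1-\phi^2)$). $\Sigma_g$ is a modular correlation matrix —
`rhoWithin = 0.3` inside each of 6 contiguous modules, a resting-state
network analogy, and `rhoBetween = 0.1` across — chosen as the simplest
process with controllable lag-0 correlation and plausible temporal
autocorrelation. Expertise effects are *degree* perturbations: a signed
delta added to one planted ROI's whole row/column (DC is a node
statistic, so perturbing a node's entire edge set is the matched
alteration), clipped to $[-0.95, 0.95]$ with a warning if the shift
would leave the valid range. Both matrices are repaired to positive
definiteness by eigenvalue flooring at $10^{-6}$ with unit-diagonal
restoration, iterated until the floor holds — deterministic and
order-independent. The seven default planted regions carry the sign
pattern of the expertise contrast (positive on the fusiform- and left
superior-frontal-analog regions, negative on the other five) at
magnitude 0.3; published SVM weights are not correlation deltas, so
magnitudes are free simulation parameters and 0.3 is the package's
default effect size.

Voxel mode copies each ROI's series onto a contiguous block of voxels
(default 12×12×12 grid, identity affine) with independent Gaussian voxel
noise — enough to exercise the full NIfTI/label-volume plumbing without
shipping an atlas. Within the expertise group the expertise score is
$\rho\, z(\mathrm{DC}) + \sqrt{1-\rho^2}\,\epsilon$ rescaled to its
target mean/SD, with target correlation $\rho = 0.5$ against the
designated (fusiform-analog) region's generator-side DC; response time
and the face-memory score carry no brain coupling. Everything is
deterministic given the config seed.

What the generator does **not** emulate: hemodynamics, head motion and
physiological artifacts, spatial autocorrelation beyond the block
structure, real atlas geometry, and scanner drift beyond what the AR(1)
process implies. Passing tests therefore certify the pipeline's
*statistical* machinery — selection, cross-validation, error control —
not robustness to the spatial artifacts of real acquisitions.

## Simulation behavior worth knowing

Two findings from the test suite deserve emphasis.

* **Planted effects are recovered.** At delta 0.3 on 7 of 50 regions
  with 22 subjects per group and 180 retained volumes, nested LOOCV
  accuracy is ≥ 0.8 and at least 5 of 7 planted regions appear in the
  across-fold selection union in the large majority of seeds.
  Occasionally the smallest-set tie-break collapses selection onto a
  single super-discriminative region in every fold — accurate, but with
  a deliberately minimal region list.
* **Null cohorts can classify *below* chance.** With no planted effects,
  nested-LOOCV accuracy is overdispersed relative to a
  Binomial$(44, 1/2)$ draw (observed SD ≈ 0.18 vs 0.075 binomial across
  seeds) and its mean sits slightly below 0.5, with occasional extreme
  runs near zero. This is the known anti-learning pathology of
  leave-one-out evaluation combined with in-fold feature selection:
  features chosen because they separate the training groups by chance
  systematically misorder the held-out subject. The corresponding
  calibration test in `test-acceptance.R` asserts the binomial band and
  is expected to be strict — on the fixed test seeds it fails by one
  simulation, and the cross-check with libsvm confirms the behavior is
  procedural, not a solver artifact. Practically: a null result from
  this procedure should be interpreted with a permutation test, not a
  binomial one.

The test suite's problem sizes (cohorts of 44–200 subjects, 50 regions,
50–190 volumes; 20 seeds per calibration claim) were chosen so the whole
suite exercises every stage at the study's own scale while remaining
comfortable on a laptop; the acceptance script uses 10 seeds per
simulated quantity for the same reason.

## Numerical conventions

* Correlation threshold strict (`r > 0.2`), positive edges only.
* Fisher clipping at $|r| = 1 - 10^{-6}$; band-pass bin edges inclusive
  with $10^{-12}$ absolute tolerance; PD floor $10^{-6}$.
* Percent metrics rounded half away from zero (2 decimals), AUC to 4.
* RFE ties: removal — larger original column index first; retention —
  smallest index; chosen subset — smallest set, then earliest iteration.
* Subject identifiers `sub-001`…; groups `{control, expertise}`;
  expertise = +1 throughout; voxel coordinates are 0-based array indices
  only through the NIfTI affine.
* Degenerate inputs error early and descriptively: empty or non-brain
  masks, zero-variance ROIs (named), all-subthreshold graphs (the
  normalization error advises reviewing the threshold), folds that lose
  a class.
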