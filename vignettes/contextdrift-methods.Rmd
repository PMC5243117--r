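---
title: "Methods: linking slow fMRI pattern drift to retrospective duration estimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking slow fMRI pattern drift to retrospective duration estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contextdrift)
```

## The scientific question and the model

People asked, from memory, how much time passed between two moments of an
experience tend to report longer durations when more "happened" in between —
when the mental context (location, situation, characters, goals) changed
more. `contextdrift` implements an analysis pipeline that operationalizes
this idea for naturalistic fMRI: while participants listen to a ~25-minute
story (1040 volumes at TR = 1.5 s), the multivoxel activity pattern of a
region is extracted around pairs of story clips, and the *pattern distance*

$$d(a, b) = 1 - r_{\mathrm{Pearson}}(\bar{p}_a, \bar{p}_b)$$

between the two clip patterns (each averaged over a 5-TR window centered on
the clip's middle volume) serves as a proxy for how far the region's
contextual representation drifted during the interval. Per participant, the
pattern distances of the retained intervals are correlated with that
participant's retrospective duration estimates; a region whose correlation
is consistently positive across participants is a candidate carrier of
temporal context.

Only 2-minute intervals enter the neural analyses: at the 6-minute scale the
pattern distances cannot be separated from low-frequency scanner noise, as
the filter-selection diagnostic below makes concrete. At TR = 1.5 s a
2-minute interval spans exactly 80 volumes, which is why the lagged distance
time course (`distance_timecourse()`) uses an 80-TR lag. The package
measures a clip pair's gap between clip *midpoints*, so the distance between
the two clip-window centers is exactly 80 TRs for every 2-minute interval.

## Inference: why phase-randomized surrogates

BOLD signals are strongly autocorrelated, so the null distribution of a
correlation between a slowly varying distance time course and 24 duration
estimates is much wider than the textbook null for 24 independent points.
`surrogate_z()` therefore builds the participant's lag-80 distance series,
samples it at each retained interval's position (the series index whose
start window is centered on the first clip's middle TR), and compares the
empirical correlation with duration estimates against the same correlation
computed on phase-randomized surrogates of the series. Surrogates share the
original amplitude spectrum exactly — hence its autocorrelation — with
phases drawn uniformly and conjugate-symmetrized so the inverse transform is
real. All correlations are Fisher-transformed (clamped at |r| = 1 - 1e-7),
and the standardized value is

$$z = \frac{\hat\rho - \mathrm{mean}(\rho_{\mathrm{null}})}{\mathrm{sd}(\rho_{\mathrm{null}})},$$

with the sample (n-1) standard deviation. One design choice deserves
emphasis: the empirical value entering `z` is computed from the same lag-80
series, sampled at the same indices, as the surrogates. This keeps the
empirical statistic exchangeable with its null — the calibration test in the
suite (type-I error within two binomial standard errors of 5% over 500 null
draws) depends on it. The clip-pair-based correlation (allowing unequal clip
durations and 6-minute gaps) remains available via `drift_behavior_corr()`.

Group-level inference is a right-tailed one-sample t-test of the
per-participant z-values per region, corrected with the two-stage linear
step-up FDR procedure (first pass at q/(1+q), re-estimation of the number of
true nulls, second pass at the adjusted level), implemented in
`bky_reject()` because no installed package provides the two-stage variant.
Reported masks use q < 0.05 for a-priori region sets and q < 0.1 for
whole-brain exploratory sets.

The within-interval analysis (`within_interval_analysis()`) transposes the
logic: distances and estimates are z-scored within participant, correlated
*across participants* separately for each interval, and each interval's
correlation is standardized against a null obtained by scrambling the
estimate-to-participant assignment. Because the z-scoring removes
participant-level location and scale, the result is invariant to affine
rescaling of any participant's estimates — a property the suite checks
directly. Effect sizes on both axes use Cohen's d = mean(r)/sd(r).

## Preprocessing

* `despike()` removes points deviating from the series mean by more than 5
  inter-quartile ranges and fills them by cubic interpolation (nearest
  surviving value at the edges).
* `highpass()` implements the Gaussian-weighted running-line filter: at
  every time point a straight line fitted under Gaussian weights of scale
  `sigma = cutoff/2` is subtracted and the series mean restored. The filter
  is a smoother, not a projection, so repeated application is only
  approximately idempotent (exact for in-band signals; a few percent on
  broadband noise), and its rolloff is gentle — a sinusoid at twice the
  cutoff period is attenuated by roughly a third, not eliminated. These are
  properties of the named algorithm, and the tests assert the measured
  behavior rather than an idealized brick-wall response.
* `nuisance_residualize()` projects out, per voxel, the mean of the top-1%
  highest-SD voxels, the mean CSF signal and the mean white-matter signal
  (plus an intercept), restoring voxel means afterwards. It runs after
  high-pass filtering.
* `select_cutoff()` encodes the filter-selection diagnostic: for each
  candidate cutoff (140-720 s), filter, residualize, and compute each
  region's inter-subject correlation (ISC, the correlation of a
  participant's region-mean time course with the average of everyone
  else's); choose the longest cutoff at which every designated grey-matter
  region's ISC significantly exceeds the CSF ISC (paired one-tailed t,
  alpha = 0.05 — the criterion is our reading of the published error bars,
  which do not state one). If no cutoff qualifies the shortest candidate is
  returned with a warning. A caveat discovered while testing: the diagnostic
  CSF region must be distinct from the nuisance CSF pool, because the pooled
  CSF mean is itself a regressor and its residual is identically zero.
* `smooth_window()` is the 5-TR centered moving average used before
  timescale profiling.

## The synthetic-data generator

`synth_config()` / `synth_dataset()` produce datasets with the statistical
structure the analysis assumes, at the study's design constants: 18
participants, 1040 TRs at 1.5 s, 86 clips of 5-10 s delimiting 43 intervals
(24 two-minute, 19 six-minute), 17 naive participants, 9 event-boundary
raters. Components:

* **Latent context walk.** Per participant and region, a 4-dimensional
  Gaussian random walk smoothed with a ~20-TR kernel (scaled by the region's
  `drift_rate`). The ground-truth contextual change of an interval is the
  Euclidean distance between the walk at the two clip midpoints, and is
  recomputable from the stored walks (`latent_displacement()`).
* **Projection to voxels.** Each voxel carries the walk along a random
  loading direction at a fixed amplitude relative to its noise SD
  (`signal_scale`, default 4.5). The per-voxel normalization is deliberate:
  it keeps variance-based nuisance pools (the top-1%-SD regressor) anchored
  to the designated high-variance "vascular" voxels rather than to the
  signal itself.
* **Noise.** AR(1) voxel noise (rho = 0.3); 2% of voxels get 5x noise SD
  and a 3x artifact loading.
* **Global artifact** (all compartments, including CSF and WM): a
  positively-loaded very slow shared process that produces spurious
  inter-subject correlation of compartment means; three weak rotational
  slow components; and an accelerating deterministic drift whose lag-80
  displacement grows over the run, so unfiltered pattern distances increase
  with story position. All components live at periods long enough that the
  480 s filter plus residualization removes them — that removability is
  precisely what the preprocessing stage is for, and the suite checks the
  CSF ISC collapses by more than half after cleanup.
* **Behavior.** Estimates follow
  `intercept + 0.5 * true_gap + effect * drift + content * dissimilarity +
  participant offset + noise`, floored at zero and reported at 1 s
  resolution. The intercept (160 s) and gap slope (0.5) put the group means
  near 3.7 and 5.7 minutes for 2- and 6-minute intervals. The drift term
  uses the standardized latent displacement of the `effect_roi`; its default
  slope (0.612 in units of 60 s per SD) makes the *true*
  displacement-estimate correlation 0.5 once the content-term variance is
  accounted for. Naive estimates depend on the content term only, which is
  the dot product of per-clip feature vectors drawn from a smooth
  story-level process (so similarity decays with story time, giving naive
  estimates a weak gap effect, as observed empirically). Boundary press
  times are drawn with rate proportional to the story-level contextual step
  size, which couples boundary counts to mean estimates through the shared
  content term. Confidence ratings (1-5) are drawn per clip with
  participant-specific calibration and are independent of accuracy by
  default.

What the generator does **not** emulate: hemodynamic convolution, head
motion, spatial autocorrelation of voxels, stimulus-locked shared neural
responses across participants (grey-matter ISC in synthetic data comes only
from the artifact), and any nonlinearity in how context maps to duration
judgments — the linear form is a modeling choice, not an empirical claim.
One visible consequence: regions with a strong latent walk show pattern
distances that *shrink* with story position in unfiltered data (the walk
escapes its origin, so late patterns share a large static component), while
the artifact pushes nuisance-compartment distances the other way. Passing
tests on this generator therefore demonstrate the statistical machinery is
calibrated and sensitive, not that real scans behave this way.

## Recovery calibration

The headline synthetic check plants the drift effect at a true
displacement-estimate correlation of 0.5 and asks the full chain
(480 s high-pass, residualization, surrogate z with 150 surrogates, group
t + two-stage FDR over the three grey regions) to flag the drift region and
spare the matched null region at q < 0.05 in at least 80 of 100 replicate
datasets. Two calibrations behind that number were fixed before the test
was frozen: the per-voxel signal amplitude (`signal_scale = 4.5`), which
sets how faithfully measured pattern distance tracks the latent displacement
(about r = 0.65-0.7 after filtering), and the family of three regions, which
keeps the adaptive FDR threshold honest — with only two hypotheses the
two-stage procedure's second pass is so lenient that a true discovery drags
the null region over the line about 10% of the time, an artifact of
family size rather than of the method.

## Mixed model

`fit_mixed()` fits, per region,

```
y ~ 1 + naive + distance + (1 + naive + distance | subject) + (1 + distance | interval)
```

where `y` is the Box-Cox-transformed duration estimate (`boxcox_lambda()`
maximizes the profile likelihood of the fixed-effects-only model over a
lambda grid from -2 to 2 in steps of 0.01, via the standard profile
likelihood machinery), `naive` is the naive group's per-interval mean (naive
participants cannot be matched to scanned participants, so their estimates
are group-averaged; consequently the naive slope varies by subject only),
and `distance` the region's pattern distance. Both covariates are
standardized over the analysis set before fitting; this stabilizes the
crossed fit and fixes the scale of the reported coefficients. The maximal
model is attempted first; on non-convergence or a singular random-effects
covariance the structure is simplified stepwise (correlations dropped, then
slopes, then intercepts only), and the ladder of attempts is recorded on
the fit object. This is the documented alternative to a weakly-regularized
Bayesian fit, which the original analysis found to give highly consistent
results; the regularized solver is not available here, so the simplification
ladder is the implementation of the convergence contract. Wald 95% intervals
come from the asymptotic Gaussian approximation; the suite checks ~95%
coverage on data generated exactly from the model. `tidy()` and `glance()`
return the coefficient table and fit summary.

## Searchlights and cluster-mass inference

`run_searchlight()` slides a cubic neighborhood (3x3x3 by default) over the
grid; centers follow a strict-interior rule (the full cube must fit in the
grid), and cube-and-mask sets smaller than `min_voxels` are skipped (use 25
with 5x5x5 cubes; group maps additionally require 5 contributing
participants, via `run_searchlight_group()`). `cluster_mass_fwe()` runs the
voxelwise right-tailed one-sample t-test across maps, labels
supra-threshold voxels (uncorrected p below the cluster-forming threshold,
0.01) by 26-connectivity, and refers each cluster's mass — the sum of
supra-threshold t — to the permutation distribution of the *maximum*
cluster mass under sign-flipping of whole maps, the standard exchangeability
argument for one-sample designs. With eight maps the full set of 256 sign
patterns is enumerated and corrected p-values are deterministic. No
variance smoothing is applied. Connected-component labeling is a small
breadth-first search written here because no installed package labels 3D
arrays.

## Timescale profiling

`pattern_acf()` correlates the multivoxel pattern at every TR with the
pattern at every other TR and averages the curves across reference TRs
aligned at lag zero (shrinking sample at long lags, no padding);
`voxel_acf()` does the univariate analogue and averages across voxels. The
FWHM is the number of lags, over a symmetric range capped at T/4, at which
the mean autocorrelation is at or above half its maximum (the maximum is 1
at lag zero). The count is two-sided: a 5-TR boxcar on white noise gives
FWHM 5 (lags -2..+2), and an AR(1) voxel with rho = 0.9 gives 13. For a
one-voxel region the pattern correlation is undefined across voxels, so
`pattern_acf()` delegates to the voxel autocorrelation there — the two
methods must agree in that degenerate case. `regress_out_size()` removes the
linear effect of region size per participant, and `compare_regions()` ranks
regions and compares pairs with the right-tailed paired Wilcoxon signed-rank
test.

## Behavioral statistics

The behavioral module reproduces the study's full battery: per-gap grand
means and the paired t-test; the high-confidence versus all-intervals
difference-score contrast; interval confidence as the minimum of the two
clip ratings with a per-participant threshold that drops at least a third
and retains at least a third of intervals (ties between equally balanced
thresholds resolve toward retaining more — the worked 8/8/8 case retains
16); the participant-resampling bootstrap CI for the correlation of mean
estimates with the mean event-boundary count; the closed-form difference
interval for two bootstrapped correlation CIs; within- versus between-group
inter-subject correlation with label-scrambling inference (equal group
sizes required, since the comparison is otherwise meaningless); split-half
reliability over random participant splits (sizes differing by at most one
for odd pools); the time-order effect (estimates against story position,
2-minute intervals by default, configurable); and timeline-placement
accuracy as the negative absolute residual of regressing estimated on
actual clip positions, which makes it invariant to affine miscalibration of
the timeline.

Two conventions adopted where the published wording is ambiguous: bootstrap
intervals use the standard percentile bounds (2.5th and 97.5th percentiles
for a 95% interval; the published percentile phrasing is internally
inconsistent), and reliability analyses default to all intervals with a
per-gap option. Coverage of the percentile bootstrap is close to nominal
for large participant pools and drifts anticonservative below ~20
participants; the suite tests it at a 40-participant pool.

## Numerical choices and problem sizes

Seconds are the internal time unit everywhere; minutes appear only in
reported tables. TR indices are 1-based. All randomness flows from one
master seed through deterministic substreams (`substream_seed()`), so
per-participant and per-region computations are reproducible regardless of
execution order. The test suite runs its simulations at sizes chosen to
exercise each guarantee meaningfully while keeping the default run
practical: 500 draws x 1000 surrogates for the size of the surrogate test,
200 replicates for FDR, FWE and mixed-model coverage (with 500 sign-flip
permutations and an 8^3 grid for the FWE check), 100 replicates at the full
generator defaults for effect recovery, and 150 surrogates per
participant-region inside that recovery loop.

## Known limitations

The generator's grey-matter regions carry no shared stimulus-driven signal,
so ISC-based filter selection on default synthetic data is only informative
for the nuisance compartments; the dedicated test constructs runs with an
explicit shared signal. Pattern distance is the only dissimilarity
implemented (no cosine or Mahalanobis variants). Hemodynamic lag between
stimulus and BOLD is not modeled, and registration across brains is assumed
done upstream — searchlight group analyses take pre-aligned grids as input.
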