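# contextdrift

Slowly changing mental context — where you are, what is happening, what you
plan to do — is thought to be bound into episodic memories, so that the
amount of contextual change between two remembered moments scales how much
time you *retrospectively* judge to have passed between them. `contextdrift`
implements, as a tested R pipeline, the analysis that links this idea to
naturalistic fMRI: multivoxel **pattern distance**

> d(a, b) = 1 − r(p̄ₐ, p̄ᵦ),

the correlation distance between a brain region's activity patterns around
two story clips (each averaged over a 5-TR window), is used as a proxy for
contextual drift during the interval between the clips, and is related to
participants' duration estimates for those intervals.

The package is aimed at cognitive-neuroscience researchers who want to run,
extend, or scrutinize this style of analysis. It provides:

- **Inference built for autocorrelated signals**: per participant and
  region, the distance–estimate correlation is standardized against
  phase-randomized surrogates of the lag-80 pattern-distance time course
  (`surrogate_z()`), z = (ρ̂ − mean ρ₀)/sd ρ₀; group-level right-tailed
  t-tests with two-stage FDR across regions (`group_roi_test()`,
  `bky_reject()`); a within-interval, across-participant permutation variant
  (`within_interval_analysis()`); Cohen's d effect sizes.
- **Whole-brain searchlights** with cluster-mass family-wise-error control
  by sign-flip permutation (`run_searchlight()`, `cluster_mass_fwe()`), and
  the timeline-accuracy encoding map (`encoding_accuracy_map()`).
- **Crossed-random-effects modeling** of duration estimates on pattern
  distance controlling for naive estimates, with a Box-Cox response
  transform and Wald intervals (`fit_mixed()`, with `tidy()`/`glance()`
  methods).
- **Timescale profiling**: pattern and voxel autocorrelation FWHM, region
  rankings, signed-rank comparisons (`pattern_acf()`, `voxel_acf()`,
  `compare_regions()`).
- **Algorithmic preprocessing**: despiking, the Gaussian running-line
  high-pass filter, nuisance residualization, ISC-based filter-cutoff
  selection (`despike()`, `highpass()`, `nuisance_residualize()`,
  `select_cutoff()`).
- **Behavioral statistics**: gap means and paired tests, confidence
  filtering, bootstrap correlation CIs, the closed-form difference interval
  for two bootstrapped correlations (`zou_difference_ci()`), within/between
  group inter-subject correlation, split-half reliability, time-order
  effects, timeline accuracy.
- **A seeded synthetic-data generator** (`synth_config()`,
  `synth_dataset()`) that embeds a known context-drift → duration-estimate
  effect plus realistic nuisance structure, so every stage of the pipeline
  is verifiable without raw scans.

## Worked example

Generate a small synthetic dataset (6 participants; the "drift" region's
latent context walk drives the simulated duration estimates, the "null"
region is a matched control), preprocess one run, and test both regions:

```r
library(contextdrift)

cfg <- synth_config(n_participants = 6, seed = 42)
ds  <- synth_dataset(cfg)

gap_means_ttest(ds$reports, ds$schedule)
#> # A tibble: 1 x 8
#>   mean_2min_min mean_6min_min sd_2min_min sd_6min_min     t    df           p
#>           <dbl>         <dbl>       <dbl>       <dbl> <dbl> <dbl>       <dbl>
#> 1          3.87          6.93       0.841       0.935  38.7     5 0.000000217

two_min <- ds$schedule$intervals$interval_id[
  ds$schedule$intervals$true_gap_s == 120]
run  <- nuisance_residualize(highpass_run(ds$runs[[1]], filter_spec(480)))
rep1 <- dplyr::filter(ds$reports, participant_id == 1)

surrogate_z(run, "drift", ds$schedule, rep1, two_min, n = 1000, seed = 7)
#> <null_ensemble> empirical 0.3283 | 1000 nulls (mean 0.0182, sd 0.2504) | z = 1.238
surrogate_z(run, "null",  ds$schedule, rep1, two_min, n = 1000, seed = 7)
#> <null_ensemble> empirical -0.0898 | 1000 nulls (mean 0.0027, sd 0.2183) | z = -0.424
```

The simulated 6-minute intervals are judged longer than the 2-minute ones
(6.93 vs 3.87 min), and in this participant the drift region's
distance–estimate correlation (Fisher z = 0.33) sits 1.24 null standard
deviations above its surrogate null while the control region sits at
−0.42. Aggregating such z-values across participants with
`group_roi_test()` flags the drift region and spares the control.

The behavioral correlation-difference interval is a one-liner; from the
published correlations of duration estimates with event-boundary counts
(original group r = 0.49, 95% CI [0.27, 0.57]; naive group r = 0.09,
[−0.05, 0.21]):

```r
zou_difference_ci(0.49, 0.27, 0.57, 0.09, -0.05, 0.21)
#> # A tibble: 1 x 3
#>   rdiff lldiff uldiff
#>   <dbl>  <dbl>  <dbl>
#> 1   0.4  0.149  0.561
```

i.e. the groups' correlations differ by 0.40 with a 95% interval of
[0.15, 0.56] at printed precision — the original participants' estimates
track event boundaries reliably more than naive guesses based on clip
content alone.

See `vignette("contextdrift-methods")` for the model, its assumptions, all
tunable parameters, and what the synthetic generator does and does not
emulate.

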