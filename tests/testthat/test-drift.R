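mk_run <- function(data, roi = "a", tr = 1.5, p = 1L) {
  structure(list(participant_id = p, data = data, tr_seconds = tr,
                 voxels = tibble::tibble(voxel = seq_len(nrow(data)),
                                         roi = roi, compartment = "grey",
                                         high_sd = FALSE),
                 latent = NULL), class = "bold_run")
}

test_that("pattern distance matches hand-computed values", {
  expect_equal(pattern_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(pattern_distance(c(1, 2, 3), c(3, 2, 1)), 2)
  expect_equal(pattern_distance(c(1, 0, 1, 0), c(1, 1, 0, 0)), 1)  # r = 0
  # symmetry and range over random patterns
  withr::with_seed(5, {
    for (i in 1:20) {
      p <- rnorm(10); q <- rnorm(10)
      d <- pattern_distance(p, q)
      expect_equal(d, pattern_distance(q, p))
      expect_true(d >= 0 && d <= 2)
    }
  })
  expect_error(pattern_distance(rep(1, 5), rnorm(5)), "constant")
})

test_that("clip patterns follow the centered-window indexing convention", {
  T_ <- 30
  data <- matrix(rep(1:T_, each = 12), 12)  # voxel value = TR index
  run <- mk_run(data)
  sched <- toy_schedule(2)
  # clip of 6 s at onset 0, TR 1.5: middle TR = round(3/1.5) = 2; the
  # centered 5-TR window {0..4} is shifted to {1..5}, mean = 3
  sched$clips$onset_s[1] <- 0
  sched$clips$duration_s[1] <- 6
  pat <- clip_pattern(run, "a", sched, 1)
  expect_equal(unname(pat), rep(mean(1:5), 12))
  # constant-in-time voxels: pattern equals any single TR
  run2 <- mk_run(matrix(rnorm(12), 12, T_))
  expect_equal(clip_pattern(run2, "a", sched, 1), run2$data[, 1])
  # small ROI is refused
  expect_error(clip_pattern(mk_run(data[1:5, , drop = FALSE]), "a", sched, 1),
               class = "contextdrift_small_roi")
})

test_that("widening the averaging window reduces noise-driven distance", {
  base <- withr::with_seed(9, rnorm(40))
  T_ <- 400
  sched <- toy_schedule(1, gap_s = 120)
  d_by_window <- vapply(c(1, 5, 9), function(w) {
    mean(vapply(1:40, function(s) {
      noise <- withr::with_seed(1000 + s, matrix(rnorm(40 * T_, sd = 1), 40))
      run <- mk_run(outer(base, rep(1, T_)) + noise)
      pattern_distance(clip_pattern(run, "a", sched, 1, window = w),
                       clip_pattern(run, "a", sched, 2, window = w))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(d_by_window) < 0))
})

test_that("distance time course has the documented length and zeros", {
  T_ <- 200
  withr::with_seed(2, {
    run <- mk_run(matrix(rnorm(20 * T_), 20))
  })
  s <- distance_timecourse(run, "a", lag = 80, window = 5)
  expect_length(s$values, T_ - 80 - 4)
  expect_equal(s$center_tr, 3:118)
  # period-80 repeating patterns: all distances 0
  block <- withr::with_seed(3, matrix(rnorm(20 * 80), 20))
  rep_run <- mk_run(do.call(cbind, replicate(3, block, simplify = FALSE)))
  s2 <- distance_timecourse(rep_run, "a", lag = 80, window = 5)
  expect_lt(max(abs(s2$values)), 1e-8)
  # white-noise voxels: mean distance near 1
  big <- mk_run(withr::with_seed(4, matrix(rnorm(60 * 600), 60)))
  s3 <- distance_timecourse(big, "a", lag = 80, window = 5)
  expect_lt(abs(mean(s3$values) - 1), 0.05)
  expect_error(distance_timecourse(mk_run(matrix(rnorm(20 * 60), 20)), "a"),
               "too short")
})

test_that("Fisher transform and clamping behave as documented", {
  expect_equal(fisher_z(0), 0)
  expect_equal(round(fisher_z(0.5), 4), 0.5493)
  expect_warning(z1 <- fisher_z(1), "clamped")
  expect_equal(z1, atanh(1 - 1e-7))
})

test_that("phase surrogates preserve the amplitude spectrum exactly", {
  x <- withr::with_seed(11, rnorm(101))
  s <- phase_surrogates(x, n = 20, seed = 4)
  amp0 <- Mod(fft(x))
  expect_lt(max(abs(sweep(Mod(mvfft(s)), 1, amp0, "-")) / max(amp0)), 1e-10)
  expect_true(is.numeric(s))  # inverse transform is real
  # constant series: only DC energy, surrogates identical
  expect_equal(phase_surrogates(rep(2.5, 32), n = 3, seed = 1),
               matrix(2.5, 32, 3))
  # pure sinusoid: variance preserved to numerical tolerance (Parseval)
  xs <- sin(2 * pi * (1:64) / 8)
  ss <- phase_surrogates(xs, n = 10, seed = 2)
  expect_lt(max(abs(apply(ss, 2, var) - var(xs))), 1e-10)
  # determinism and even/odd lengths
  expect_identical(phase_surrogates(x, 5, seed = 9),
                   phase_surrogates(x, 5, seed = 9))
  xe <- withr::with_seed(12, rnorm(100))
  se <- phase_surrogates(xe, n = 5, seed = 3)
  expect_lt(max(abs(Mod(mvfft(se)) - Mod(fft(xe)))), 1e-8)
})

test_that("null ensembles standardize with the sample sd convention", {
  ne <- null_ensemble(0.3, c(0.1, 0.2, 0.3))
  expect_equal(ne$z, (0.3 - 0.2) / sd(c(0.1, 0.2, 0.3)))
  expect_equal(round(ne$z, 4), 1)  # sample sd 0.1
  expect_equal(null_ensemble(0.2, c(0.1, 0.2, 0.3))$z, 0)
  expect_error(null_ensemble(0.5, rep(0.2, 10)), "zero spread")
  td <- tidy(ne)
  expect_equal(td$n_nulls, 3)
})

test_that("surrogate z detects planted association and is calibrated-ish", {
  ds <- synth_dataset(small_cfg(seed = 13))
  two_min <- ds$schedule$intervals$interval_id[
    ds$schedule$intervals$true_gap_s == 120]
  rp <- dplyr::filter(ds$reports, participant_id == 1)
  run <- nuisance_residualize(highpass_run(ds$runs[[1]], filter_spec(480)))
  # estimates proportional to the sampled distances: z large and positive
  s <- distance_timecourse(run, "drift")
  idx <- contextdrift:::interval_series_index(s, ds$schedule, two_min)
  rp2 <- tibble::tibble(interval_id = two_min,
                        estimate_s = 100 + 100 * s$values[idx])
  ne <- suppressWarnings(  # perfect correlation is clamped for atanh
    surrogate_z(run, "drift", ds$schedule, rp2, two_min, n = 300, seed = 5))
  expect_gt(ne$z, 3)
  expect_equal(ne$empirical, atanh(1 - 1e-7))
  # constant estimates error
  expect_error(
    surrogate_z(run, "drift", ds$schedule,
                tibble::tibble(interval_id = two_min, estimate_s = 100),
                two_min, n = 10, seed = 1),
    "constant")
})

test_that("two-stage FDR rejects and ranks sensibly", {
  expect_true(all(bky_reject(rep(1e-4, 10), 0.05)))
  expect_false(any(bky_reject(runif(20, 0.5, 1), 0.05)))
  # two-stage is at least as powerful as plain BH on a mixed family
  p <- c(0.001, 0.004, 0.01, 0.02, 0.3, 0.5, 0.7, 0.9)
  expect_gte(sum(bky_reject(p, 0.05)), sum(p.adjust(p, "BH") <= 0.05))
  # q-values are the smallest level at which each hypothesis is rejected
  q <- contextdrift:::bky_qvalue(p)
  for (i in seq_along(p)) {
    expect_true(bky_reject(p, q[i] + 1e-4)[i])
    if (q[i] > 2e-4) expect_false(bky_reject(p, q[i] - 1e-4)[i])
  }
})

test_that("group ROI test aggregates z-values with FDR masks", {
  z_tbl <- tibble::tibble(
    roi = rep(c("a", "b", "c"), each = 10),
    participant_id = rep(1:10, 3),
    z = c(rep(0, 10), withr::with_seed(1, rnorm(10, 3)), rep(NA_real_, 10))
  )
  expect_message(res <- group_roi_test(z_tbl), "excluding")
  expect_equal(sort(res$roi), c("a", "b"))
  a <- res[res$roi == "a", ]
  expect_equal(a$t, 0)
  expect_equal(a$p, 0.5)
  expect_false(a$sig_q05)
  expect_true(res$sig_q05[res$roi == "b"])
})

test_that("within-interval analysis is invariant to participant affine scaling", {
  withr::with_seed(21, {
    n_p <- 8; n_i <- 10
    dist_tbl <- tidyr::crossing(participant_id = 1:n_p, interval_id = 1:n_i) |>
      dplyr::mutate(distance = rnorm(dplyr::n(), 1, 0.3))
    est_tbl <- dist_tbl |>
      dplyr::mutate(estimate_s = 200 + 80 * distance + rnorm(dplyr::n(), 0, 20)) |>
      dplyr::select(-distance)
  })
  r1 <- within_interval_analysis(dist_tbl, est_tbl, n_perm = 200, seed = 3)
  # per-participant affine rescaling of estimates changes nothing
  est2 <- est_tbl |>
    dplyr::group_by(participant_id) |>
    dplyr::mutate(estimate_s = estimate_s * participant_id + 1000 * participant_id) |>
    dplyr::ungroup()
  r2 <- within_interval_analysis(dist_tbl, est2, n_perm = 200, seed = 3)
  expect_equal(r1$per_interval$r, r2$per_interval$r)
  expect_equal(r1$group$t, r2$group$t)
  expect_gt(r1$group$t, 2)  # planted association is found
  # estimates equal to distances: every interval r = 1 (clamped for the
  # Fisher transform, hence the warnings)
  est3 <- dist_tbl |> dplyr::rename(estimate_s = distance)
  r3 <- suppressWarnings(
    within_interval_analysis(dist_tbl, est3, n_perm = 50, seed = 1))
  expect_true(all(r3$per_interval$r > 1 - 1e-8))
  # intervals with too few participants are skipped with a message
  expect_message(
    r4 <- within_interval_analysis(dist_tbl[-(1:6), ], est_tbl[-(1:6), ],
                                   n_perm = 50, seed = 1,
                                   min_participants = 8),
    "skipped")
  expect_true(is.na(r4$per_interval$z[1]))
})

test_that("Cohen's d is mean over sd of the correlations", {
  expect_equal(cohens_d(c(0.1, 0.3)), 0.2 / sd(c(0.1, 0.3)))
  expect_equal(round(cohens_d(c(0.1, 0.3)), 3), 1.414)
  expect_equal(cohens_d(c(-0.2, 0.2)), 0)
  expect_error(cohens_d(rep(0.5, 4)), "zero")
  expect_error(cohens_d(0.5), "2 values")
})

test_that("story-position correlations behave on constructed cases", {
  sched <- toy_schedule(10)
  reports <- toy_reports(5, 10, fn = function(p, i) 500 - 30 * i)
  # distances independent of position: group mean r(dist) near 0 over reps
  rs <- vapply(1:40, function(s) {
    dist_tbl <- withr::with_seed(s, tidyr::crossing(participant_id = 1:5,
                                                    interval_id = 1:10) |>
                                   dplyr::mutate(distance = rnorm(dplyr::n())))
    story_position_drift(dist_tbl, reports, sched)$mean_r[1]
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
  # estimates built to decay with position: negative estimate correlation
  dist_tbl <- tidyr::crossing(participant_id = 1:5, interval_id = 1:10) |>
    dplyr::mutate(distance = 1)
  dist_tbl$distance <- withr::with_seed(1, rnorm(nrow(dist_tbl)))
  res <- story_position_drift(dist_tbl, reports, sched)
  expect_lt(res$mean_r[res$metric == "estimate"], -0.9)
})

test_that("unfiltered synthetic data drift apart as the run progresses", {
  # the scanner-drift artifact makes the lag-80 distance series trend
  # upward in the nuisance compartments before any filtering
  ds <- synth_dataset(small_cfg(seed = 17, n_trs = 700L))
  trend <- vapply(ds$runs[1:4], function(r) {
    s1 <- distance_timecourse(r, "csf", min_voxels = 5)
    s2 <- distance_timecourse(r, "wm", min_voxels = 5)
    cor(s1$center_tr, (s1$values + s2$values) / 2)
  }, numeric(1))
  expect_true(all(trend > 0))
})
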