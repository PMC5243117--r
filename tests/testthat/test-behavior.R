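test_that("interval confidence is the minimum of the two clip ratings", {
  sched <- toy_schedule(4)
  conf <- tibble::tibble(
    participant_id = 1L,
    clip_id = c(sched$intervals$clip_a, sched$intervals$clip_b),
    confidence = c(5L, 1L, 1L, 0L, 3L, 1L, 4L, 1L)
  )
  ic <- interval_confidence(conf, sched)
  expect_equal(ic$confidence, pmin(c(5, 1, 1, 0), c(3, 1, 4, 1)))
  # missing clip rating flags the interval
  expect_warning(
    ic2 <- interval_confidence(conf[-1, ], sched),
    "missing"
  )
  expect_true(is.na(ic2$confidence[1]))
})

test_that("confidence filter satisfies both one-third constraints", {
  sched24 <- toy_schedule(24)
  # balanced binary: retain exactly the high-confidence half
  ic <- tibble::tibble(participant_id = 1L, interval_id = 1:24,
                       confidence = rep(c(0L, 1L), each = 12))
  f <- confidence_filter(ic)
  expect_equal(sum(f$retained), 12)
  expect_true(all(f$retained[ic$confidence == 1]))

  # all ratings equal: infeasible, retain all with warning
  ic2 <- ic |> dplyr::mutate(confidence = 3L)
  expect_warning(f2 <- confidence_filter(ic2), "no feasible")
  expect_true(all(f2$retained))

  # {1x8, 3x8, 5x8}: both candidate thresholds are feasible and equally
  # balanced; the tie goes to retaining more (16)
  ic3 <- ic |> dplyr::mutate(confidence = rep(c(1L, 3L, 5L), each = 8))
  f3 <- confidence_filter(ic3)
  expect_equal(sum(f3$retained), 16)

  # property: whenever any threshold is feasible, the choice drops >= 1/3
  # and retains >= 1/3 (exhaustive check against enumeration)
  withr::with_seed(42, {
    for (i in 1:30) {
      conf <- sample(1:5, 43, replace = TRUE)
      ic4 <- tibble::tibble(participant_id = 1L, interval_id = 1:43,
                            confidence = conf)
      feasible <- any(vapply(2:5, function(c) {
        d <- sum(conf < c); d >= 43 / 3 && (43 - d) >= 43 / 3
      }, logical(1)))
      if (feasible) {
        f4 <- confidence_filter(ic4)
        expect_gte(sum(!f4$retained), 43 / 3)
        expect_gte(sum(f4$retained), 43 / 3)
      } else {
        expect_warning(f4 <- confidence_filter(ic4))
        expect_true(all(f4$retained))
      }
    }
  })
})

test_that("gap means and paired t behave on degenerate and noiseless input", {
  sched <- toy_schedule(6)
  sched$intervals$true_gap_s <- rep(c(120, 360), each = 3)
  # identical estimates across gaps: difference 0, t = 0
  rep_flat <- toy_reports(4, 6, fn = function(p, i) 200)
  gm <- gap_means_ttest(rep_flat, sched)
  expect_equal(gm$mean_2min_min, gm$mean_6min_min)
  expect_equal(gm$t, 0)
  expect_equal(gm$p, 1)
})

test_that("difference-score contrast errors on identical subsets", {
  sched <- toy_schedule(6)
  sched$intervals$true_gap_s <- rep(c(120, 360), each = 3)
  reports <- toy_reports(4, 6)
  expect_error(difference_score_contrast(reports, sched, NULL, NULL),
               "identical")
})

test_that("bootstrap correlation CI is sane and errors on bad input", {
  sched <- toy_schedule(8)
  reports <- toy_reports(6, 8, fn = function(p, i) 100 + 20 * i + 7 * p)
  cov <- tibble::tibble(interval_id = 1:8, covariate = 1:8)
  res <- bootstrap_corr_ci(reports, cov, n_boot = 200, seed = 2)
  expect_equal(res$r, 1)  # mean estimates are affine in the covariate
  expect_true(res$ll <= res$r & res$r <= res$ul)
  # constant covariate errors
  expect_error(
    bootstrap_corr_ci(reports,
                      tibble::tibble(interval_id = 1:8, covariate = 1),
                      n_boot = 10, seed = 1),
    "constant")
  # fewer than 3 intervals errors
  expect_error(
    bootstrap_corr_ci(dplyr::filter(reports, interval_id <= 2),
                      cov, n_boot = 10, seed = 1),
    "3 intervals")
})

test_that("bootstrap CI coverage is near nominal on synthetic data", {
  # participants share a linear signal in the covariate plus noise; the
  # estimand is the large-replicate mean correlation of the participant-
  # averaged estimates with the covariate at this pool size, computed by
  # simulation. The percentile bootstrap approaches nominal coverage as the
  # participant pool grows; a 40-participant pool is used here.
  n_p <- 40; n_i <- 12
  cov <- tibble::tibble(interval_id = 1:n_i,
                        covariate = seq(-1, 1, length.out = n_i))
  gen <- function(seed) {
    withr::with_seed(seed, {
      est <- outer(rep(1, n_p), 15 * cov$covariate) +
        matrix(rnorm(n_p * n_i, sd = 60), n_p, n_i)
      tibble::tibble(participant_id = rep(1:n_p, each = n_i),
                     interval_id = rep(1:n_i, n_p),
                     estimate_s = 300 + as.numeric(t(est)))
    })
  }
  rs <- vapply(1:400, function(s) {
    bootstrap_corr_ci(gen(10000 + s), cov, n_boot = 2, seed = 1)$r
  }, numeric(1))
  r_pop <- mean(rs)
  covered <- vapply(1:300, function(s) {
    ci <- bootstrap_corr_ci(gen(s), cov, n_boot = 400, seed = s)
    ci$ll <= r_pop && r_pop <= ci$ul
  }, logical(1))
  expect_gt(mean(covered), 0.90)
  expect_lt(mean(covered), 1.0)
})

test_that("correlation-difference CI reproduces its closed form", {
  # worked example from the printed correlations
  z <- zou_difference_ci(0.49, 0.27, 0.57, 0.09, -0.05, 0.21)
  expect_equal(round(z$rdiff, 2), 0.40)
  expect_equal(round(z$lldiff, 2), 0.15)
  expect_equal(round(z$uldiff, 2), 0.56)
  # identical inputs: symmetric interval around 0
  z2 <- zou_difference_ci(0.3, 0.1, 0.5, 0.3, 0.1, 0.5)
  expect_equal(z2$rdiff, 0)
  expect_equal(z2$lldiff, -z2$uldiff)
  # ordering property over random valid inputs
  withr::with_seed(7, {
    for (i in 1:50) {
      r <- sort(runif(6, -1, 1))
      z3 <- zou_difference_ci(r[5], r[4], r[6], r[2], r[1], r[3])
      expect_true(z3$lldiff <= z3$rdiff && z3$rdiff <= z3$uldiff)
    }
  })
  # violated ordering errors
  expect_error(zou_difference_ci(0.5, 0.6, 0.7, 0, -0.1, 0.1), "ll <= r")
})

test_that("ISC within vs between groups is exchangeable for identical groups", {
  reports <- toy_reports(6, 10, fn = function(p, i) {
    100 + 15 * i + 10 * p * (i %% 2)
  })
  res <- isc_within_between(reports, reports, n_perm = 200, seed = 3)
  expect_equal(res$isc_a, res$isc_b)
  expect_gt(res$p, 0.5)
  # unequal sizes are rejected
  expect_error(
    isc_within_between(reports, dplyr::filter(reports, participant_id > 1),
                       n_perm = 10, seed = 1),
    "equal")
})

test_that("ISC permutation p-value is uniform under the null", {
  # both groups drawn from one generator: empirical CDF of p at several
  # cutpoints within binomial tolerance of uniform over 200 datasets
  n_sets <- 200
  ps <- vapply(seq_len(n_sets), function(s) {
    withr::with_seed(s, {
      est <- matrix(rnorm(12 * 10, sd = 1), 12, 10) +
        outer(rep(1, 12), rnorm(10))  # shared interval signal, no groups
      reports <- tibble::tibble(
        participant_id = rep(1:12, each = 10),
        interval_id = rep(1:10, 12),
        estimate_s = as.numeric(t(est)))
    })
    a <- dplyr::filter(reports, participant_id <= 6)
    b <- dplyr::filter(reports, participant_id > 6)
    isc_within_between(a, b, n_perm = 99, seed = s)$p
  }, numeric(1))
  for (q in c(0.25, 0.5, 0.75)) {
    tol <- 3 * sqrt(q * (1 - q) / n_sets)
    expect_lt(abs(mean(ps <= q) - q), tol + 1 / 100)
  }
})

test_that("split-half reliability hits its limiting cases", {
  # identical participants: every split correlates perfectly
  reports <- toy_reports(6, 8, fn = function(p, i) 50 * i)
  sh <- split_half_reliability(reports, n_splits = 50, seed = 1)
  expect_equal(sh$mean_r, 1)
  expect_equal(sh$sd_r, 0)
  # independent noise: mean split-half r near 0 across datasets
  ms <- vapply(1:40, function(s) {
    noise <- withr::with_seed(s, toy_reports(10, 12,
                                             fn = function(p, i) rnorm(1, 300, 60)))
    split_half_reliability(noise, n_splits = 50, seed = s)$mean_r
  }, numeric(1))
  expect_lt(abs(mean(ms)), 0.1)
  expect_error(split_half_reliability(toy_reports(2, 8), n_splits = 5),
               "4 participants")
})

test_that("time-order effect recovers monotone structure", {
  sched <- toy_schedule(8)
  # strictly decreasing estimates in position for every participant
  dec <- toy_reports(5, 8, fn = function(p, i) 600 - 40 * i + 5 * p)
  res <- time_order_effect(dec, sched)
  per <- attr(res, "per_participant")
  expect_true(all(per$r < 0))
  expect_lt(res$t, 0)
  # estimates independent of position: mean r near 0 over replicates
  rs <- vapply(1:60, function(s) {
    r <- withr::with_seed(s, toy_reports(5, 8, fn = function(p, i) rnorm(1, 300, 50)))
    time_order_effect(r, sched)$mean_r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("timeline accuracy is affine-invariant with exact placements", {
  sched <- toy_schedule(10)
  actual <- sched$clips$onset_s + sched$clips$duration_s / 2
  pl <- tibble::tibble(participant_id = 1L, clip_id = sched$clips$clip_id,
                       placed_s = actual)
  res <- timeline_accuracy(pl, sched)
  expect_equal(res$per_participant$r, 1)
  expect_true(all(abs(res$per_clip$error) < 1e-8))
  # affine map of placements absorbed by the regression
  pl2 <- pl |> dplyr::mutate(placed_s = 2 * placed_s + 5)
  res2 <- timeline_accuracy(pl2, sched)
  expect_equal(res2$per_participant$r, 1)
  expect_true(all(abs(res2$per_clip$error) < 1e-8))
  # random placements carry no information on average
  rs <- vapply(1:50, function(s) {
    p3 <- withr::with_seed(s, pl |> dplyr::mutate(placed_s = runif(dplyr::n(), 0, 1500)))
    timeline_accuracy(p3, sched)$per_participant$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.15)
})
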