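# The central computation: clip-pattern extraction, pattern dissimilarity,
# surrogate-tested within-participant correlation with duration estimates,
# within-interval permutation analysis, two-stage FDR over regions, effect
# sizes.

roi_voxel_idx <- function(run, roi) {
  run$voxels$voxel[run$voxels$roi == roi]
}

#' Average multivoxel pattern around a clip
#'
#' The clip's middle TR is `round((onset + duration/2) / TR)` (1-based); the
#' pattern is the mean over the `window` consecutive TRs centered on it, the
#' window being shifted (not shrunk) to fit inside the run at the edges.
#'
#' @param run A `bold_run`.
#' @param roi ROI label (must have at least `min_voxels` voxels).
#' @param schedule A `clip_schedule`.
#' @param clip_id Clip identifier.
#' @param window Window length in TRs (odd).
#' @param min_voxels Minimum ROI size; smaller ROIs raise a condition the
#'   caller may convert into a recorded missing value.
#' @return Numeric voxel pattern.
#' @export
clip_pattern <- function(run, roi, schedule, clip_id, window = 5,
                         min_voxels = 10) {
  vox <- roi_voxel_idx(run, roi)
  if (length(vox) < min_voxels) {
    abort(sprintf("roi '%s' has fewer than %d voxels", roi, min_voxels),
          class = "contextdrift_small_roi")
  }
  clip <- schedule$clips[schedule$clips$clip_id == clip_id, ]
  if (nrow(clip) != 1) abort(sprintf("unknown clip_id %s", clip_id))
  mid <- clip_middle_tr(clip$onset_s, clip$duration_s, run$tr_seconds)
  half <- (window - 1) / 2
  T_ <- ncol(run$data)
  idx <- mid + (-half:half)
  if (idx[1] < 1) idx <- idx - idx[1] + 1
  if (idx[window] > T_) idx <- idx - (idx[window] - T_)
  if (idx[1] < 1) abort("clip window out of range")
  rowMeans(run$data[vox, idx, drop = FALSE])
}

#' Pattern dissimilarity (1 - Pearson correlation)
#'
#' @param p,q Voxel patterns of equal length (>= 2), non-constant.
#' @return Dissimilarity in \[0, 2\].
#' @export
pattern_distance <- function(p, q) {
  if (length(p) != length(q) || length(p) < 2) {
    abort("patterns must have equal length >= 2")
  }
  1 - safe_cor(p, q, "pattern")
}

#' Clip-pair pattern distances for a participant
#'
#' @param run A `bold_run`.
#' @param roi ROI label.
#' @param schedule A `clip_schedule`.
#' @param interval_ids Intervals to evaluate (default all).
#' @param window,min_voxels Passed to [clip_pattern()].
#' @return Tibble: `participant_id`, `interval_id`, `distance` (`NA` if the
#'   ROI is below `min_voxels`).
#' @export
drift_distance_table <- function(run, roi, schedule, interval_ids = NULL,
                                 window = 5, min_voxels = 10) {
  ints <- schedule$intervals
  if (!is.null(interval_ids)) {
    ints <- ints %>% filter(.data$interval_id %in% interval_ids)
  }
  d <- tryCatch({
    vapply(seq_len(nrow(ints)), function(i) {
      pattern_distance(
        clip_pattern(run, roi, schedule, ints$clip_a[i], window, min_voxels),
        clip_pattern(run, roi, schedule, ints$clip_b[i], window, min_voxels)
      )
    }, numeric(1))
  }, contextdrift_small_roi = function(e) rep(NA_real_, nrow(ints)))
  tibble(participant_id = run$participant_id,
         interval_id = ints$interval_id, distance = d)
}

#' Within-participant correlation of pattern distance with estimates
#'
#' Per retained interval, the pattern distance between the two clip patterns
#' is correlated with the participant's duration estimates; the Pearson r is
#' Fisher-transformed (clamped at |r| = 1 - 1e-7).
#'
#' @param run,roi,schedule As in [drift_distance_table()].
#' @param reports The participant's reports tibble (`interval_id`,
#'   `estimate_s`).
#' @param retained Interval ids to use (>= 3); default all in `reports`.
#' @param window,min_voxels Passed through.
#' @return One-row tibble: `participant_id`, `roi`, `n_intervals`, `r`,
#'   `fisher_z`; the per-interval distances in attribute `"distances"`.
#' @export
drift_behavior_corr <- function(run, roi, schedule, reports, retained = NULL,
                                window = 5, min_voxels = 10) {
  retained <- retained %||% reports$interval_id
  if (length(retained) < 3) abort("need at least 3 retained intervals")
  est <- reports$estimate_s[match(retained, reports$interval_id)]
  if (sd(est) == 0) abort("constant estimates: correlation undefined")
  dt <- drift_distance_table(run, roi, schedule, retained, window, min_voxels)
  r <- if (all(is.na(dt$distance))) NA_real_ else cor(dt$distance, est)
  out <- tibble(participant_id = run$participant_id, roi = roi,
                n_intervals = length(retained), r = r,
                fisher_z = fisher_z(r))
  attr(out, "distances") <- dt %>% mutate(estimate_s = est)
  out
}

#' Lagged pattern-distance time course
#'
#' For each valid start the dissimilarity between the window-averaged pattern
#' centered there and the one `lag` TRs later; valid starts are those where
#' both centered windows fit, giving `T - lag - (window - 1)` values.
#'
#' @param run,roi As elsewhere.
#' @param lag Lag in TRs (default 80 = 2 min at TR 1.5 s).
#' @param window Averaging window (TRs).
#' @param min_voxels Minimum ROI size.
#' @return A `distance_series`: list with `values`, `center_tr` (window
#'   centers, 1-based), `lag_trs`, `window_trs`.
#' @export
distance_timecourse <- function(run, roi, lag = 80, window = 5,
                                min_voxels = 10) {
  vox <- roi_voxel_idx(run, roi)
  if (length(vox) < min_voxels) {
    abort(sprintf("roi '%s' has fewer than %d voxels", roi, min_voxels),
          class = "contextdrift_small_roi")
  }
  X <- run$data[vox, , drop = FALSE]
  T_ <- ncol(X)
  if (T_ <= lag + window) abort("run too short for requested lag and window")
  A <- smooth_window(X, window)
  half <- (window - 1) / 2
  centers <- (half + 1):(T_ - lag - half)
  As <- scale(A)  # column-standardized patterns
  v <- 1 - colSums(As[, centers, drop = FALSE] *
                     As[, centers + lag, drop = FALSE]) / (nrow(As) - 1)
  structure(list(values = as.numeric(v), center_tr = centers,
                 lag_trs = lag, window_trs = window),
            class = "distance_series")
}

#' Phase-randomized surrogates of a series
#'
#' Discrete Fourier transform; each positive frequency's phase is replaced
#' by an independent uniform draw on \[0, 2*pi), negative frequencies take
#' the conjugate-symmetric phases, DC (and the Nyquist bin for even length)
#' stay untouched; the inverse transform returns real surrogates sharing the
#' original amplitude spectrum (hence autocorrelation).
#'
#' @param x Numeric series (length >= 8).
#' @param n Number of surrogates.
#' @param seed RNG seed.
#' @return Matrix `length(x)` x `n`, one surrogate per column.
#' @export
phase_surrogates <- function(x, n = 10000, seed = 1) {
  N <- length(x)
  if (N < 8) abort("series too short for phase randomization")
  X <- fft(x)
  half <- floor((N - 1) / 2)
  S <- matrix(complex(real = rep(0, N * n)), N, n)
  S[1, ] <- X[1]
  if (half >= 1) {
    phases <- with_seed(seed, matrix(runif(half * n, 0, 2 * pi), half, n))
    amp <- Mod(X[2:(half + 1)])
    pos <- amp * exp(1i * phases)
    S[2:(half + 1), ] <- pos
    S[N:(N - half + 1), ] <- Conj(pos)
  }
  if (N %% 2 == 0) S[N / 2 + 1, ] <- X[N / 2 + 1]
  Re(mvfft(S, inverse = TRUE)) / N
}

#' Empirical statistic with its null ensemble
#'
#' Standardizes an empirical value against a null distribution:
#' `z = (empirical - mean(nulls)) / sd(nulls)` with the sample (n-1)
#' standard deviation.
#'
#' @param empirical Empirical (Fisher-transformed) statistic.
#' @param nulls Numeric vector of null statistics.
#' @return An object of class `null_ensemble` (fields `empirical`, `nulls`,
#'   `z`).
#' @export
null_ensemble <- function(empirical, nulls) {
  s <- sd(nulls)
  if (!is.finite(s) || s == 0) abort("null distribution has zero spread")
  structure(list(empirical = empirical, nulls = nulls,
                 z = (empirical - mean(nulls)) / s),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> empirical %.4f | %d nulls (mean %.4f, sd %.4f) | z = %.3f\n",
              x$empirical, length(x$nulls), mean(x$nulls), sd(x$nulls), x$z))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.null_ensemble <- function(x, ...) {
  tibble(empirical = x$empirical, null_mean = mean(x$nulls),
         null_sd = sd(x$nulls), n_nulls = length(x$nulls), z = x$z)
}

# Map retained intervals to indices of the lag-`lag` distance series: each
# interval's index is the series position whose start window is centered on
# clip_a's middle TR.
interval_series_index <- function(series, schedule, retained) {
  ints <- schedule$intervals %>% filter(.data$interval_id %in% retained)
  mids <- clip_middle_tr(
    schedule$clips$onset_s[match(ints$clip_a, schedule$clips$clip_id)],
    schedule$clips$duration_s[match(ints$clip_a, schedule$clips$clip_id)],
    schedule$tr_seconds
  )
  idx <- match(mids, series$center_tr)
  if (anyNA(idx)) abort("interval clip window falls outside the distance series")
  idx[match(retained, ints$interval_id)]
}

#' Phase-surrogate z for the distance-estimate correlation
#'
#' Builds the participant's lag-80 distance time course, samples it at each
#' retained interval's clip-a-centered position, and correlates with the
#' duration estimates: the empirical value. The same sampling applied to
#' `n` phase-randomized surrogates of the series yields the null
#' correlations; all correlations are Fisher-transformed and the z-value is
#' the empirical value standardized against the null.
#'
#' @param run,roi,schedule,reports,retained As in [drift_behavior_corr()].
#' @param n Number of surrogates.
#' @param seed RNG seed.
#' @param lag,window,min_voxels Passed to [distance_timecourse()].
#' @return A [null_ensemble()].
#' @export
surrogate_z <- function(run, roi, schedule, reports, retained = NULL,
                        n = 10000, seed = 1, lag = 80, window = 5,
                        min_voxels = 10) {
  retained <- retained %||% reports$interval_id
  if (length(retained) < 3) abort("need at least 3 retained intervals")
  est <- reports$estimate_s[match(retained, reports$interval_id)]
  if (sd(est) == 0) abort("constant estimates: correlation undefined")
  series <- distance_timecourse(run, roi, lag = lag, window = window,
                                min_voxels = min_voxels)
  idx <- interval_series_index(series, schedule, retained)
  emp <- fisher_z(safe_cor(series$values[idx], est, "distance series"))
  surr <- phase_surrogates(series$values, n = n, seed = seed)
  nulls <- as.numeric(cor(est, surr[idx, , drop = FALSE]))
  nulls <- fisher_z(nulls, warn_clamp = FALSE)
  null_ensemble(emp, nulls)
}

#' Two-stage FDR (Benjamini-Krieger-Yekutieli) decisions
#'
#' Stage one runs linear step-up (BH) at `q' = q/(1+q)`; unless it rejects
#' none or all, the number of true nulls is re-estimated as `m - r1` and a
#' second BH pass is run at `q' * m / (m - r1)`.
#'
#' @param p Vector of p-values.
#' @param q Target FDR level.
#' @return Logical rejection vector.
#' @export
bky_reject <- function(p, q = 0.05) {
  m <- length(p)
  q1 <- q / (1 + q)
  bh <- function(p, level) p.adjust(p, "BH") <= level
  r1 <- sum(bh(p, q1))
  if (r1 == 0) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  bh(p, q1 * m / (m - r1))
}

# Smallest q at which a hypothesis is rejected by the two-stage procedure
# (bisection; the rejection set is monotone in q).
bky_qvalue <- function(p) {
  vapply(seq_along(p), function(i) {
    lo <- 0; hi <- 1
    for (it in 1:30) {
      mid <- (lo + hi) / 2
      if (bky_reject(p, mid)[i]) hi <- mid else lo <- mid
    }
    hi
  }, numeric(1))
}

#' Group-level test of surrogate z-values per region
#'
#' One-sample right-tailed t-test of the per-participant z-values against 0
#' for each region, with two-stage FDR correction across regions. Masks are
#' reported at q < 0.05 (a-priori region sets) and q < 0.1 (whole-brain
#' exploratory sets).
#'
#' @param z_table Tibble: `roi`, one row per participant (or interval) with
#'   column `z` (missing values allowed).
#' @param min_n Minimum non-missing values per region.
#' @return Tibble: `roi`, `n`, `mean_z`, `t`, `df`, `p`, `q`, `sig_q05`,
#'   `sig_q10`. Regions with fewer than `min_n` values are excluded with a
#'   message.
#' @export
group_roi_test <- function(z_table, min_n = 3) {
  by_roi <- z_table %>%
    filter(!is.na(.data$z)) %>%
    group_by(.data$roi) %>%
    summarise(n = dplyr::n(), mean_z = mean(.data$z), sd_z = sd(.data$z),
              .groups = "drop")
  dropped <- setdiff(unique(z_table$roi), by_roi$roi[by_roi$n >= min_n])
  if (length(dropped) > 0) {
    inform(sprintf("excluding region(s) with too few values: %s",
                   paste(dropped, collapse = ", ")))
  }
  by_roi <- by_roi %>% filter(.data$n >= min_n)
  stats_tbl <- by_roi %>%
    mutate(t = dplyr::case_when(
             .data$sd_z > 0 ~ .data$mean_z / (.data$sd_z / sqrt(.data$n)),
             .data$mean_z == 0 ~ 0,
             TRUE ~ sign(.data$mean_z) * Inf
           ),
           df = .data$n - 1,
           p = pt(.data$t, .data$df, lower.tail = FALSE))
  stats_tbl %>%
    mutate(q = bky_qvalue(.data$p),
           sig_q05 = bky_reject(.data$p, 0.05),
           sig_q10 = bky_reject(.data$p, 0.10)) %>%
    select("roi", "n", "mean_z", "t", "df", "p", "q", "sig_q05", "sig_q10")
}

#' Within-interval (across participants) correlation analysis
#'
#' Distances and estimates are z-scored within participant across that
#' participant's retained intervals; for each interval the Pearson
#' correlation across participants between distance and estimate is compared
#' with a null obtained by scrambling the estimate-to-participant assignment
#' within the interval. A right-tailed t-test aggregates the per-interval
#' z-values.
#'
#' @param dist_table Tibble: `participant_id`, `interval_id`, `distance`
#'   (retained rows only).
#' @param est_table Tibble: `participant_id`, `interval_id`, `estimate_s`
#'   (same retained rows).
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @param min_participants Minimum participants retaining an interval.
#' @return List: `per_interval` tibble (`interval_id`, `n`, `r`, `z`),
#'   `group` one-row tibble (`mean_z`, `t`, `df`, `p`), `cohens_d` of the
#'   per-interval correlations.
#' @export
within_interval_analysis <- function(dist_table, est_table, n_perm = 10000,
                                     seed = 1, min_participants = 3) {
  df <- dplyr::inner_join(dist_table, est_table,
                          by = c("participant_id", "interval_id")) %>%
    filter(!is.na(.data$distance)) %>%
    group_by(.data$participant_id) %>%
    mutate(zd = as.numeric(scale(.data$distance)),
           ze = as.numeric(scale(.data$estimate_s))) %>%
    ungroup()
  ints <- sort(unique(df$interval_id))
  per <- purrr::map_dfr(seq_along(ints), function(k) {
    sub <- df %>% filter(.data$interval_id == ints[k])
    m <- nrow(sub)
    if (m < min_participants) {
      return(tibble(interval_id = ints[k], n = m, r = NA_real_,
                    z = NA_real_))
    }
    d <- sub$zd; e <- sub$ze
    if (sd(d) == 0 || sd(e) == 0) {
      return(tibble(interval_id = ints[k], n = m, r = NA_real_,
                    z = NA_real_))
    }
    r_emp <- cor(d, e)
    ds <- (d - mean(d)) / sd(d); es <- (e - mean(e)) / sd(e)
    perm_idx <- with_seed(substream_seed(seed, 11, k), {
      matrix(replicate(n_perm, sample.int(m)), m, n_perm)
    })
    nulls <- colSums(ds * matrix(es[perm_idx], m, n_perm)) / (m - 1)
    ne <- null_ensemble(fisher_z(r_emp), fisher_z(nulls, warn_clamp = FALSE))
    tibble(interval_id = ints[k], n = m, r = r_emp, z = ne$z)
  })
  skipped <- sum(is.na(per$z))
  if (skipped > 0) {
    inform(sprintf("skipped %d interval(s) with too few retaining participants",
                   skipped))
  }
  ok <- per %>% filter(!is.na(.data$z))
  tt <- t.test(ok$z, alternative = "greater")
  list(per_interval = per,
       group = tibble(mean_z = mean(ok$z), t = unname(tt$statistic),
                      df = unname(tt$parameter), p = tt$p.value),
       cohens_d = cohens_d(ok$r))
}

#' Cohen's d of a set of correlations
#'
#' `mean(r) / sd(r)` across participants (within-participant analysis) or
#' intervals (within-interval analysis).
#'
#' @param r_values Numeric vector (length >= 2, non-constant).
#' @return Scalar effect size.
#' @export
cohens_d <- function(r_values) {
  r_values <- r_values[!is.na(r_values)]
  if (length(r_values) < 2) abort("need at least 2 values")
  s <- sd(r_values)
  if (s == 0) abort("zero standard deviation: d undefined")
  mean(r_values) / s
}

#' Story-position correlations of distances and estimates
#'
#' Per participant, the Pearson correlation of interval position in the
#' story with (a) pattern distance and (b) duration estimate, each followed
#' by a group-level one-sample two-sided t-test.
#'
#' @param dist_table Tibble: `participant_id`, `interval_id`, `distance`.
#' @param reports Reports tibble.
#' @param schedule A `clip_schedule`.
#' @param gap_s True-gap subset (default 120 s).
#' @return Tibble with rows `distance` and `estimate`: `mean_r`, `sd_r`,
#'   `t`, `df`, `p`; per-participant correlations in attribute
#'   `"per_participant"`.
#' @export
story_position_drift <- function(dist_table, reports, schedule,
                                 gap_s = 120) {
  ints <- schedule$intervals %>% filter(.data$true_gap_s %in% gap_s)
  df <- dist_table %>%
    dplyr::inner_join(reports %>% select("participant_id", "interval_id",
                                         "estimate_s"),
                      by = c("participant_id", "interval_id")) %>%
    dplyr::inner_join(ints %>% select("interval_id", "position_s"),
                      by = "interval_id") %>%
    filter(!is.na(.data$distance))
  per <- df %>%
    group_by(.data$participant_id) %>%
    summarise(r_distance = cor(.data$position_s, .data$distance),
              r_estimate = cor(.data$position_s, .data$estimate_s),
              .groups = "drop")
  row_for <- function(x, label) {
    tt <- onesample_t(x)
    tibble(metric = label, mean_r = mean(x), sd_r = sd(x),
           t = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value)
  }
  out <- bind_rows(row_for(per$r_distance, "distance"),
                   row_for(per$r_estimate, "estimate"))
  attr(out, "per_participant") <- per
  out
}
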