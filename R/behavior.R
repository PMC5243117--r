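# Behavioral analyses: group means and tests, confidence filtering, bootstrap
# CIs, correlation-difference CIs, inter-subject and split-half reliability,
# time-order effect, timeline accuracy.
#
# Table schemas used throughout:
#   reports:         participant_id, interval_id, estimate_s (+ true_gap_s)
#   clip confidence: participant_id, clip_id, confidence
#   schedule:        clip_schedule (clips + intervals tibbles)

#' Per-interval confidence from per-clip ratings
#'
#' An interval's confidence is the smaller of the ratings of the two clips
#' delimiting it. Works for ordinal (1-5) and binary (0/1) ratings.
#'
#' @param clip_confidence Tibble: `participant_id`, `clip_id`, `confidence`.
#' @param schedule A `clip_schedule`.
#' @return Tibble: `participant_id`, `interval_id`, `confidence`. Intervals
#'   with a missing clip rating get `NA` and are flagged with a warning.
#' @export
interval_confidence <- function(clip_confidence, schedule) {
  ints <- schedule$intervals
  out <- clip_confidence %>%
    distinct(.data$participant_id) %>%
    tidyr::crossing(ints %>% select("interval_id", "clip_a", "clip_b")) %>%
    left_join(clip_confidence %>% rename(conf_a = "confidence"),
              by = c("participant_id", clip_a = "clip_id")) %>%
    left_join(clip_confidence %>% rename(conf_b = "confidence"),
              by = c("participant_id", clip_b = "clip_id")) %>%
    mutate(confidence = pmin(.data$conf_a, .data$conf_b)) %>%
    select("participant_id", "interval_id", "confidence") %>%
    arrange(.data$participant_id, .data$interval_id)
  if (anyNA(out$confidence)) {
    warn(sprintf("%d interval(s) flagged missing: absent clip rating",
                 sum(is.na(out$confidence))))
  }
  out
}

#' Confidence-based interval filter
#'
#' Picks, per participant, the confidence threshold `c` that drops intervals
#' with confidence < `c` such that at least one third of intervals are
#' dropped and at least one third retained; among feasible thresholds the one
#' whose retained fraction is closest to 1/2 wins, ties going to the smaller
#' threshold (retain more). If no threshold is feasible (e.g. all ratings
#' equal) all intervals are retained with a warning.
#'
#' @param interval_conf Tibble from [interval_confidence()].
#' @return The input with columns `retained` (logical) and `threshold`.
#' @export
confidence_filter <- function(interval_conf) {
  res <- interval_conf %>%
    group_by(.data$participant_id) %>%
    dplyr::group_modify(function(df, key) {
      conf <- df$confidence
      ok <- !is.na(conf)
      n <- sum(ok)
      cands <- sort(unique(conf[ok]))[-1]  # smallest level can never drop
      feas <- purrr::keep(cands, function(c) {
        dropped <- sum(conf[ok] < c)
        dropped >= n / 3 && (n - dropped) >= n / 3
      })
      if (length(feas) == 0) {
        warn(sprintf(
          "participant %s: no feasible confidence threshold; retaining all",
          as.character(key$participant_id)))
        thr <- -Inf
      } else {
        bal <- vapply(feas, function(c) abs(sum(conf[ok] >= c) / n - 0.5),
                      numeric(1))
        thr <- feas[which.min(bal)]  # which.min takes the first = smaller c
      }
      df %>% mutate(retained = !is.na(conf) & conf >= thr, threshold = thr)
    }) %>%
    ungroup()
  res
}

per_participant_gap_means <- function(reports, schedule, subset = NULL) {
  df <- reports %>%
    select(-dplyr::any_of("true_gap_s")) %>%
    left_join(schedule$intervals %>% select("interval_id", "true_gap_s"),
              by = "interval_id")
  if (!is.null(subset)) {
    df <- df %>%
      dplyr::semi_join(subset %>% filter(.data$retained),
                       by = c("participant_id", "interval_id"))
  }
  df %>%
    group_by(.data$participant_id, .data$true_gap_s) %>%
    summarise(mean_est_s = mean(.data$estimate_s), .groups = "drop")
}

#' Grand means per true gap and paired t-test
#'
#' Averages estimates within participant for each true gap (2 min / 6 min),
#' then across participants, and runs a paired two-sided t-test on the
#' per-participant (6-min mean - 2-min mean) differences.
#'
#' @param reports Duration reports tibble.
#' @param schedule A `clip_schedule`.
#' @param subset Optional retained-interval tibble from [confidence_filter()].
#' @return One-row tibble: `mean_2min_min`, `mean_6min_min` (minutes),
#'   `sd_2min_min`, `sd_6min_min`, `t`, `df`, `p`, `n_participants`.
#' @export
gap_means_ttest <- function(reports, schedule, subset = NULL) {
  pm <- per_participant_gap_means(reports, schedule, subset)
  wide <- pm %>%
    tidyr::pivot_wider(names_from = "true_gap_s", values_from = "mean_est_s",
                       names_prefix = "gap_")
  if (!all(c("gap_120", "gap_360") %in% names(wide))) {
    abort("both 2-min and 6-min intervals are required")
  }
  incomplete <- !complete.cases(wide[c("gap_120", "gap_360")])
  if (any(incomplete)) {
    inform(sprintf("excluding %d participant(s) with no retained interval at some gap",
                   sum(incomplete)))
    wide <- wide[!incomplete, ]
  }
  if (nrow(wide) < 2) abort("need at least 2 participants")
  d <- wide$gap_360 - wide$gap_120
  tt <- if (sd(d) == 0) {
    # degenerate case: constant difference scores
    list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
         parameter = length(d) - 1,
         p.value = if (mean(d) == 0) 1 else 0)
  } else {
    t.test(wide$gap_360, wide$gap_120, paired = TRUE)
  }
  tibble(
    mean_2min_min = mean(wide$gap_120) / 60,
    mean_6min_min = mean(wide$gap_360) / 60,
    sd_2min_min = sd(wide$gap_120) / 60,
    sd_6min_min = sd(wide$gap_360) / 60,
    t = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, n_participants = nrow(wide)
  )
}

#' Contrast of duration-difference scores under two interval subsets
#'
#' The difference score is each participant's (6-min mean - 2-min mean);
#' computed under subsets A and B (e.g. high-confidence vs all intervals) and
#' compared with a paired two-sided t-test.
#'
#' @param reports,schedule As in [gap_means_ttest()].
#' @param subset_a,subset_b Retained-interval tibbles (`NULL` = all
#'   intervals).
#' @return One-row tibble: `mean_a_min`, `sd_a_min`, `mean_b_min`,
#'   `sd_b_min`, `t`, `df`, `p`.
#' @export
difference_score_contrast <- function(reports, schedule,
                                      subset_a = NULL, subset_b = NULL) {
  score <- function(subset) {
    per_participant_gap_means(reports, schedule, subset) %>%
      tidyr::pivot_wider(names_from = "true_gap_s",
                         values_from = "mean_est_s", names_prefix = "gap_") %>%
      mutate(score = (.data$gap_360 - .data$gap_120) / 60) %>%
      select("participant_id", "score")
  }
  ab <- dplyr::inner_join(score(subset_a), score(subset_b),
                          by = "participant_id", suffix = c("_a", "_b"))
  d <- ab$score_a - ab$score_b
  if (sd(d) == 0) abort("identical difference scores under both subsets: t undefined")
  tt <- t.test(ab$score_a, ab$score_b, paired = TRUE)
  tibble(mean_a_min = mean(ab$score_a), sd_a_min = sd(ab$score_a),
         mean_b_min = mean(ab$score_b), sd_b_min = sd(ab$score_b),
         t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Bootstrap CI for the correlation of mean estimates with a covariate
#'
#' Correlates participant-averaged per-interval estimates with an interval
#' covariate (e.g. mean event-boundary count). Participants are resampled
#' with replacement `n_boot` times; the interval bounds are the standard
#' percentile bounds (2.5th and 97.5th percentile for `level = 0.95`).
#'
#' @param reports Duration reports tibble.
#' @param covariate Tibble: `interval_id`, `covariate`.
#' @param n_boot Number of bootstrap samples.
#' @param level Confidence level.
#' @param seed RNG seed.
#' @return One-row tibble: `r`, `ll`, `ul`, `n_participants`, `n_intervals`.
#' @export
bootstrap_corr_ci <- function(reports, covariate, n_boot = 1000,
                              level = 0.95, seed = 1) {
  est <- reports %>%
    tidyr::pivot_wider(id_cols = "participant_id",
                       names_from = "interval_id",
                       values_from = "estimate_s") %>%
    arrange(.data$participant_id)
  ids <- as.integer(names(est)[-1])
  cov <- covariate$covariate[match(ids, covariate$interval_id)]
  if (anyNA(cov)) abort("covariate missing for some intervals")
  if (length(ids) < 3) abort("need at least 3 intervals")
  m <- as.matrix(est[-1])
  r <- safe_cor(colMeans(m), cov, "covariate or estimates")
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      take <- sample.int(nrow(m), nrow(m), replace = TRUE)
      mu <- colMeans(m[take, , drop = FALSE])
      if (sd(mu) == 0) return(NA_real_)
      cor(mu, cov)
    }, numeric(1))
  })
  alpha <- 1 - level
  qs <- quantile(boots, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                 names = FALSE)
  tibble(r = r, ll = qs[1], ul = qs[2],
         n_participants = nrow(m), n_intervals = length(ids))
}

#' Difference between two correlations from their bootstrap CIs
#'
#' Given two correlations and their confidence bounds, returns the
#' correlation difference `rdiff = r1 - r2` with bounds
#' `lldiff = rdiff - sqrt((r1-ll1)^2 + (ul2-r2)^2)` and
#' `uldiff = rdiff + sqrt((ul1-r1)^2 + (r2-ll2)^2)`.
#'
#' @param r1,ll1,ul1 First correlation and its CI bounds.
#' @param r2,ll2,ul2 Second correlation and its CI bounds.
#' @return One-row tibble: `rdiff`, `lldiff`, `uldiff`.
#' @export
zou_difference_ci <- function(r1, ll1, ul1, r2, ll2, ul2) {
  if (!(ll1 <= r1 && r1 <= ul1 && ll2 <= r2 && r2 <= ul2)) {
    abort("each correlation must satisfy ll <= r <= ul")
  }
  rdiff <- r1 - r2
  tibble(
    rdiff = rdiff,
    lldiff = rdiff - sqrt((r1 - ll1)^2 + (ul2 - r2)^2),
    uldiff = rdiff + sqrt((ul1 - r1)^2 + (r2 - ll2)^2)
  )
}

# participants x intervals estimate matrix (rows named by participant)
estimate_matrix <- function(reports) {
  wide <- reports %>%
    tidyr::pivot_wider(id_cols = "participant_id",
                       names_from = "interval_id",
                       values_from = "estimate_s") %>%
    arrange(.data$participant_id)
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$participant_id
  m
}

isc_of_groups <- function(a, b) {
  # within-group ISC: corr(own estimates, mean of others in same group);
  # between-group ISC: corr(own estimates, other group's mean)
  within <- function(m) {
    tot <- colSums(m)
    mean(vapply(seq_len(nrow(m)), function(i) {
      cor(m[i, ], (tot - m[i, ]) / (nrow(m) - 1))
    }, numeric(1)))
  }
  between <- function(m, other_mean) {
    mean(apply(m, 1, cor, y = other_mean))
  }
  wa <- within(a); wb <- within(b)
  bt <- mean(c(between(a, colMeans(b)), between(b, colMeans(a))))
  c(within_a = wa, within_b = wb, between = bt)
}

#' Within- vs between-group inter-subject correlation of estimates
#'
#' Within-group ISC is the mean over participants of the correlation between
#' their own per-interval estimates and the mean of the other members of
#' their group; between-group ISC correlates each participant with the other
#' group's mean. Significance of (mean within - between) comes from
#' scrambling group labels.
#'
#' @param reports_a,reports_b Reports tibbles for the two groups (equal
#'   sizes required for comparability).
#' @param n_perm Number of label permutations.
#' @param seed RNG seed.
#' @return One-row tibble: `isc_a`, `isc_b`, `isc_between`, `diff`, `p`.
#' @export
isc_within_between <- function(reports_a, reports_b, n_perm = 10000,
                               seed = 1) {
  a <- estimate_matrix(reports_a)
  b <- estimate_matrix(reports_b)
  if (nrow(a) != nrow(b)) {
    abort("group sizes must be equal: within/between ISCs are only comparable for identical group sizes")
  }
  if (!identical(colnames(a), colnames(b))) {
    abort("both groups must rate the same intervals")
  }
  emp <- isc_of_groups(a, b)
  emp_diff <- mean(emp[c("within_a", "within_b")]) - emp["between"]
  all_m <- rbind(a, b)
  n <- nrow(a)
  null_diff <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(2 * n)
      s <- isc_of_groups(all_m[idx[1:n], , drop = FALSE],
                         all_m[idx[(n + 1):(2 * n)], , drop = FALSE])
      mean(s[c("within_a", "within_b")]) - s["between"]
    }, numeric(1))
  })
  tibble(isc_a = unname(emp["within_a"]), isc_b = unname(emp["within_b"]),
         isc_between = unname(emp["between"]), diff = unname(emp_diff),
         p = (1 + sum(null_diff >= emp_diff)) / (1 + n_perm))
}

#' Split-half reliability of per-interval mean estimates
#'
#' Randomly splits participants into two halves (sizes differing by at most
#' one), averages per-interval estimates within each half and correlates the
#' two mean vectors; repeated over `n_splits` random splits.
#'
#' @param reports Reports tibble.
#' @param gap_s Optional true-gap subset (e.g. 120); `NULL` uses all
#'   intervals.
#' @param schedule Needed when `gap_s` is given and reports lack
#'   `true_gap_s`.
#' @param n_splits Number of random splits.
#' @param seed RNG seed.
#' @return One-row tibble: `mean_r`, `sd_r`, `n_splits`.
#' @export
split_half_reliability <- function(reports, gap_s = NULL, schedule = NULL,
                                   n_splits = 1000, seed = 1) {
  df <- reports
  if (!is.null(gap_s)) {
    if (!"true_gap_s" %in% names(df)) {
      df <- df %>% left_join(schedule$intervals %>%
                               select("interval_id", "true_gap_s"),
                             by = "interval_id")
    }
    df <- df %>% filter(.data$true_gap_s == gap_s)
  }
  m <- estimate_matrix(df)
  if (nrow(m) < 4) abort("need at least 4 participants")
  if (ncol(m) < 2) abort("need at least 2 intervals")
  n <- nrow(m)
  h <- floor(n / 2)
  rs <- with_seed(seed, {
    vapply(seq_len(n_splits), function(i) {
      idx <- sample.int(n)
      cor(colMeans(m[idx[1:h], , drop = FALSE]),
          colMeans(m[idx[(h + 1):n], , drop = FALSE]))
    }, numeric(1))
  })
  tibble(mean_r = mean(rs), sd_r = sd(rs), n_splits = n_splits)
}

#' Time-order effect: estimates vs position in story
#'
#' Per participant, the Pearson correlation between duration estimates and
#' the interval's chronological midpoint position, followed by a one-sample
#' two-sided t-test across participants.
#'
#' @param reports Reports tibble.
#' @param schedule A `clip_schedule` (provides `position_s`).
#' @param gap_s True-gap subset, default 120 s (2-min intervals).
#' @return One-row tibble: `mean_r`, `sd_r`, `t`, `df`, `p`, plus the
#'   per-participant correlations in attribute `"per_participant"`.
#' @export
time_order_effect <- function(reports, schedule, gap_s = 120) {
  ints <- schedule$intervals
  if (!is.null(gap_s)) ints <- ints %>% filter(.data$true_gap_s %in% gap_s)
  if (sd(ints$position_s) == 0) abort("interval positions are constant")
  df <- reports %>%
    dplyr::inner_join(ints %>% select("interval_id", "position_s"),
                      by = "interval_id")
  per <- df %>%
    group_by(.data$participant_id) %>%
    summarise(r = safe_cor(.data$estimate_s, .data$position_s, "estimates"),
              .groups = "drop")
  tt <- onesample_t(per$r)
  out <- tibble(mean_r = mean(per$r), sd_r = sd(per$r),
                t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value)
  attr(out, "per_participant") <- per
  out
}

#' Timeline placement accuracy
#'
#' Per participant, regresses the estimated timeline position of each clip on
#' its actual position; a clip's error is the absolute residual and its
#' accuracy the negative error (affine mis-calibrations of the timeline are
#' absorbed by the regression). Also reports each participant's Pearson
#' correlation between actual and estimated positions.
#'
#' @param placements Tibble: `participant_id`, `clip_id`, `placed_s`.
#' @param schedule A `clip_schedule` (actual positions = clip midpoints).
#' @return List with tibbles `per_clip` (`participant_id`, `clip_id`,
#'   `error`, `accuracy`) and `per_participant` (`participant_id`, `r`).
#' @export
timeline_accuracy <- function(placements, schedule) {
  actual <- schedule$clips %>%
    mutate(actual_s = .data$onset_s + .data$duration_s / 2) %>%
    select("clip_id", "actual_s")
  if (nrow(actual) < 3) abort("need at least 3 clips")
  if (sd(actual$actual_s) == 0) abort("actual positions have zero variance")
  df <- placements %>% left_join(actual, by = "clip_id")
  per_clip <- df %>%
    group_by(.data$participant_id) %>%
    dplyr::group_modify(function(d, key) {
      fit <- lm(placed_s ~ actual_s, data = d)
      d %>% mutate(error = abs(resid(fit)), accuracy = -abs(resid(fit)))
    }) %>%
    ungroup() %>%
    select("participant_id", "clip_id", "error", "accuracy")
  per_participant <- df %>%
    group_by(.data$participant_id) %>%
    summarise(r = safe_cor(.data$actual_s, .data$placed_s, "placements"),
              .groups = "drop")
  list(per_clip = per_clip, per_participant = per_participant)
}

#' Event-boundary counts per interval
#'
#' Counts, for each rater, the button presses falling between the midpoints
#' of the two clips delimiting each interval, and averages over raters.
#'
#' @param boundaries Tibble: `rater`, `press_time_s`.
#' @param schedule A `clip_schedule`.
#' @param gap_s Optional true-gap subset.
#' @return Tibble: `interval_id`, `covariate` (mean boundary count).
#' @export
boundary_counts <- function(boundaries, schedule, gap_s = NULL) {
  ints <- schedule$intervals
  if (!is.null(gap_s)) ints <- ints %>% filter(.data$true_gap_s %in% gap_s)
  clips <- schedule$clips
  mid <- clips$onset_s + clips$duration_s / 2
  n_raters <- dplyr::n_distinct(boundaries$rater)
  counts <- vapply(seq_len(nrow(ints)), function(i) {
    lo <- mid[ints$clip_a[i]]; hi <- mid[ints$clip_b[i]]
    sum(boundaries$press_time_s >= lo & boundaries$press_time_s < hi)
  }, numeric(1))
  tibble(interval_id = ints$interval_id, covariate = counts / n_raters)
}
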