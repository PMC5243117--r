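# Synthetic multi-participant datasets with a known embedded context-drift
# signal. The generator emulates the statistical structure the analysis
# assumes: a slow latent "context" walk per region whose per-interval
# displacement drives simulated duration estimates, clip-content similarity
# driving naive estimates, event-boundary presses tied to contextual change,
# and nuisance compartments (CSF-like, WM-like, high-variance voxels) sharing
# a global low-frequency artifact.

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Gaussian kernel smoothing of the columns of a matrix (or a vector), with
# edge renormalization so the smoother preserves local level near boundaries.
gauss_smooth <- function(x, sd_pts) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  half <- max(1L, ceiling(4 * sd_pts))
  k <- stats::dnorm(seq(-half, half), sd = sd_pts)
  n <- nrow(x)
  pad <- matrix(0, half, ncol(x))
  xp <- rbind(pad, x, pad)
  ones <- c(rep(0, half), rep(1, n), rep(0, half))
  sm <- apply(xp, 2, function(col) {
    as.numeric(stats::filter(col, k, sides = 2))[(half + 1):(half + n)]
  })
  norm <- as.numeric(stats::filter(ones, k, sides = 2))[(half + 1):(half + n)]
  out <- sweep(matrix(sm, nrow = n), 1, norm, "/")
  if (vec) drop(out) else out
}

#' Default region specification for the synthetic generator
#'
#' Five compartments: a grey-matter region carrying the context-drift signal
#' ("drift"), a matched grey null region ("null"), a second grey region with
#' intermediate drift ("aux"), and white-matter-like and CSF-like nuisance
#' compartments that carry no neural drift but share the global artifact.
#'
#' @return A tibble with columns `label`, `n_voxels`, `drift_rate`,
#'   `noise_sd`, `compartment`.
#' @export
default_roi_specs <- function() {
  tibble(
    label       = c("drift", "null", "aux", "wm", "csf"),
    n_voxels    = c(80L, 80L, 80L, 60L, 60L),
    drift_rate  = c(1, 0, 0.5, 0, 0),
    noise_sd    = c(1, 1, 1, 1, 1),
    compartment = c("grey", "grey", "grey", "white", "csf")
  )
}

#' Configuration for a synthetic drift/duration dataset
#'
#' Defaults mirror the design of the study the pipeline targets: 18
#' participants, 1040 volumes at TR = 1.5 s, 86 clips of 5-10 s delimiting 43
#' intervals (24 spaced 2 min apart, 19 spaced 6 min apart), duration
#' estimates around a gap slope of 0.5 with a 160 s intercept (so 2-min
#' intervals average roughly 3.7 min and 6-min intervals roughly 5.7 min),
#' and a drift effect calibrated so the within-participant distance-estimate
#' correlation in the drift region is about 0.5.
#'
#' @param n_participants Number of scanned participants.
#' @param n_trs Volumes per run.
#' @param tr_seconds Sampling period (s).
#' @param n_intervals_2min,n_intervals_6min Interval counts per true gap.
#' @param clip_duration_range_s Min/max clip duration (s).
#' @param roi_specs Tibble as returned by [default_roi_specs()].
#' @param effect_roi Label of the region whose latent displacement drives
#'   estimates.
#' @param effect_size Slope (in units of 60 s per SD of displacement) of the
#'   estimate on standardized latent drift displacement.
#' @param content_effect Slope (same units) on standardized clip-content
#'   dissimilarity; drives the naive estimates alone.
#' @param confidence_noise SD of the ordinal confidence noise.
#' @param global_drift_amplitude Amplitude of the shared low-frequency
#'   artifact added to every compartment (0 disables it).
#' @param gap_slope Slope of the estimate on the true gap (unitless).
#' @param intercept_s,naive_intercept_s Baseline estimates (s).
#' @param participant_sd_s SD of per-participant offsets (s).
#' @param estimate_noise_sd_s SD of trial noise on estimates (s).
#' @param n_naive Number of naive participants.
#' @param n_boundary_raters Number of event-boundary raters.
#' @param boundary_rate_per_min Mean button presses per minute per rater.
#' @param signal_scale Amplitude of the projected latent signal relative to
#'   voxel noise SD.
#' @param high_sd_fraction Fraction of voxels given inflated variance.
#' @param seed Master seed; all substreams derive from it deterministically.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_participants = 18L,
                         n_trs = 1040L,
                         tr_seconds = 1.5,
                         n_intervals_2min = 24L,
                         n_intervals_6min = 19L,
                         clip_duration_range_s = c(5, 10),
                         roi_specs = default_roi_specs(),
                         effect_roi = "drift",
                         effect_size = 0.612,
                         content_effect = 0.35,
                         confidence_noise = 1,
                         global_drift_amplitude = 0.5,
                         gap_slope = 0.5,
                         intercept_s = 160,
                         naive_intercept_s = 330,
                         participant_sd_s = 60,
                         estimate_noise_sd_s = 60,
                         n_naive = 17L,
                         n_boundary_raters = 9L,
                         boundary_rate_per_min = 0.9,
                         signal_scale = 4.5,
                         high_sd_fraction = 0.02,
                         seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants), n_trs = as.integer(n_trs),
    tr_seconds = tr_seconds,
    n_intervals_2min = as.integer(n_intervals_2min),
    n_intervals_6min = as.integer(n_intervals_6min),
    clip_duration_range_s = clip_duration_range_s,
    roi_specs = as_tibble(roi_specs), effect_roi = effect_roi,
    effect_size = effect_size, content_effect = content_effect,
    confidence_noise = confidence_noise,
    global_drift_amplitude = global_drift_amplitude,
    gap_slope = gap_slope, intercept_s = intercept_s,
    naive_intercept_s = naive_intercept_s,
    participant_sd_s = participant_sd_s,
    estimate_noise_sd_s = estimate_noise_sd_s,
    n_naive = as.integer(n_naive),
    n_boundary_raters = as.integer(n_boundary_raters),
    boundary_rate_per_min = boundary_rate_per_min,
    signal_scale = signal_scale,
    high_sd_fraction = high_sd_fraction,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  counts <- c(cfg$n_participants, cfg$n_trs,
              cfg$n_intervals_2min + cfg$n_intervals_6min)
  if (any(counts <= 0)) abort("all counts must be positive")
  if (cfg$tr_seconds <= 0) abort("tr_seconds must be positive")
  if (any(cfg$roi_specs$n_voxels < 10)) {
    abort("roi voxel counts must be >= 10")
  }
  if (!cfg$effect_roi %in% cfg$roi_specs$label) {
    abort(sprintf("effect_roi '%s' not among roi_specs labels", cfg$effect_roi))
  }
  run_s <- cfg$n_trs * cfg$tr_seconds
  longest <- max(c(120, 360)[c(cfg$n_intervals_2min, cfg$n_intervals_6min) > 0])
  if (longest + 2 * max(cfg$clip_duration_range_s) > run_s) {
    abort("clip schedule cannot fit within n_trs * tr_seconds")
  }
  invisible(cfg)
}

#' Generate a clip schedule
#'
#' Places 43 interval-delimiting clip pairs (by default 24 with a true gap of
#' 120 s and 19 with 360 s) inside the run. The true gap is measured between
#' clip midpoints, so a 120 s gap corresponds to exactly 80 TRs between the
#' two pattern-window centers at TR = 1.5 s. Intervals are ordered
#' chronologically; an interval's "position in story" is the midpoint between
#' its two clips.
#'
#' @param cfg A [synth_config()].
#' @return A `clip_schedule`: list with tibbles `clips`
#'   (`clip_id`, `onset_s`, `duration_s`) and `intervals`
#'   (`interval_id`, `clip_a`, `clip_b`, `true_gap_s`, `position_s`), plus
#'   `tr_seconds` and `n_trs`.
#' @export
generate_schedule <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  run_s <- cfg$n_trs * cfg$tr_seconds
  gaps <- c(rep(120, cfg$n_intervals_2min), rep(360, cfg$n_intervals_6min))
  n_int <- length(gaps)
  rng <- cfg$clip_duration_range_s
  # keep pattern windows (5 TRs) and the lag-80 series in range
  margin <- 6 * cfg$tr_seconds
  with_seed(substream_seed(cfg$seed, 101), {
    dur_a <- runif(n_int, rng[1], rng[2])
    dur_b <- runif(n_int, rng[1], rng[2])
    lo <- pmax(dur_a / 2, margin)
    hi <- run_s - gaps - pmax(dur_b / 2, margin) - margin
    if (any(hi < lo)) abort("schedule error: intervals do not fit in the run")
    mid_a <- runif(n_int, lo, hi)
  })
  mid_b <- mid_a + gaps
  ints <- tibble(
    true_gap_s = gaps, mid_a = mid_a, mid_b = mid_b,
    dur_a = dur_a, dur_b = dur_b,
    position_s = (mid_a + mid_b) / 2
  ) %>%
    arrange(.data$position_s) %>%
    mutate(interval_id = dplyr::row_number())
  clips <- bind_rows(
    ints %>% select(interval_id, mid = "mid_a", duration_s = "dur_a") %>%
      mutate(which = "a"),
    ints %>% select(interval_id, mid = "mid_b", duration_s = "dur_b") %>%
      mutate(which = "b")
  ) %>%
    mutate(onset_s = .data$mid - .data$duration_s / 2) %>%
    arrange(.data$onset_s) %>%
    mutate(clip_id = dplyr::row_number())
  ints <- ints %>%
    left_join(clips %>% filter(.data$which == "a") %>%
                select("interval_id", clip_a = "clip_id"),
              by = "interval_id") %>%
    left_join(clips %>% filter(.data$which == "b") %>%
                select("interval_id", clip_b = "clip_id"),
              by = "interval_id")
  sched <- list(
    clips = clips %>% select("clip_id", "onset_s", "duration_s"),
    intervals = ints %>%
      select("interval_id", "clip_a", "clip_b", "true_gap_s", "position_s"),
    tr_seconds = cfg$tr_seconds,
    n_trs = cfg$n_trs
  )
  structure(sched, class = "clip_schedule")
}

# Latent context walk for one region: k-dimensional Gaussian random walk
# smoothed with a ~20 TR kernel, giving slow drift with controllable
# per-interval displacement.
latent_walk <- function(n_trs, drift_rate, k = 4L, smooth_sd = 6) {
  if (drift_rate == 0) return(matrix(0, n_trs, k))
  steps <- matrix(rnorm(n_trs * k, sd = drift_rate), n_trs, k)
  gauss_smooth(apply(steps, 2, cumsum), smooth_sd)
}

# Shared low-frequency artifact: k very slow smooth walks (kernel ~150 s at
# TR 1.5 s, concentrating power at periods beyond the 480 s cutoff) whose
# step size grows over the run. The first walk is given positive voxel
# loadings (a common global component that produces spurious inter-subject
# correlation of compartment means); the remaining walks get zero-mean
# loadings and rotate the voxel pattern within a slow subspace, so
# unfiltered pattern distances increase with story position in every
# compartment -- the signature of scanner drift the high-pass /
# residualization stages must remove.
global_artifact <- function(n_trs, seed, k = 4L) {
  with_seed(substream_seed(seed, 202), {
    innov <- matrix(rnorm(n_trs * k, sd = 1 + (seq_len(n_trs) - 1) / n_trs),
                    n_trs, k)
    # mean-reverting slow processes: magnitude stays stationary while the
    # direction of the artifact subspace turns faster as innovations grow
    g <- matrix(stats::filter(innov, 0.99, method = "recursive"), n_trs, k)
    g <- gauss_smooth(g, 45)
    # plus an accelerating deterministic drift (voxel-specific once loaded):
    # its lag-80 displacement grows over the run, so unfiltered pattern
    # distances increase with story position in every compartment
    trend <- (seq_len(n_trs) / n_trs)^1.7
    g <- scale(g)
    # column 1 is the positively-loaded carrier of spurious inter-subject
    # correlation; the remaining rotational components and the accelerating
    # trend perturb the voxel pattern itself
    cbind(g[, 1], 0.2 * g[, -1, drop = FALSE],
          3 * as.numeric(scale(trend)))
  })
}

#' Generate synthetic BOLD runs
#'
#' Each region's voxel time series is a shared latent slow walk (region drift
#' rate, low-pass character) projected onto fixed random loadings, plus AR(1)
#' voxel noise, plus a global low-frequency artifact added to every
#' compartment including CSF and WM. A small fraction of voxels receives
#' inflated variance ("high-SD" voxels) and a stronger artifact loading.
#'
#' @param cfg A [synth_config()].
#' @param schedule A `clip_schedule` from [generate_schedule()].
#' @return List of `bold_run` objects, one per participant, each with fields
#'   `participant_id`, `data` (voxel x time matrix), `tr_seconds`, `voxels`
#'   (tibble: `voxel`, `roi`, `compartment`, `high_sd`), `latent` (named list
#'   of per-region latent walks).
#' @export
generate_bold <- function(cfg, schedule) {
  stopifnot(inherits(cfg, "synth_config"), inherits(schedule, "clip_schedule"))
  T_ <- cfg$n_trs
  g <- global_artifact(T_, cfg$seed) * cfg$global_drift_amplitude
  specs <- cfg$roi_specs
  purrr::map(seq_len(cfg$n_participants), function(p) {
    blocks <- purrr::pmap(specs, function(label, n_voxels, drift_rate,
                                          noise_sd, compartment) {
      s <- substream_seed(cfg$seed, 303, p, match(label, specs$label))
      with_seed(s, {
        lat <- latent_walk(T_, drift_rate)
        load <- matrix(rnorm(n_voxels * ncol(lat), sd = 1), n_voxels)
        sig <- load %*% t(lat)
        # fix every voxel's signal amplitude relative to its noise (random
        # loading direction, constant SNR), so variance-based nuisance pools
        # pick up vascular (high-SD) voxels rather than the signal itself
        vsd <- apply(sig, 1, sd)
        if (any(vsd > 0)) {
          sig[vsd > 0, ] <- sig[vsd > 0, , drop = FALSE] *
            (cfg$signal_scale * noise_sd / vsd[vsd > 0])
        }
        # AR(1) voxel noise, rho = 0.3 (recursive filter runs columnwise)
        eps <- matrix(rnorm(n_voxels * T_, sd = noise_sd), n_voxels, T_)
        noise <- t(matrix(stats::filter(t(eps), 0.3, method = "recursive"),
                          T_, n_voxels))
        n_hi <- max(if (cfg$high_sd_fraction > 0) 1L else 0L,
                    round(cfg$high_sd_fraction * n_voxels))
        hi <- rep(FALSE, n_voxels)
        if (n_hi > 0) hi[sample.int(n_voxels, n_hi)] <- TRUE
        noise[hi, ] <- noise[hi, , drop = FALSE] * 5
        g_load <- cbind(runif(n_voxels, 0.5, 1.5),
                        matrix(rnorm(n_voxels * (ncol(g) - 1)),
                               n_voxels))
        g_load[hi, ] <- g_load[hi, , drop = FALSE] * 3
        dat <- sig + noise + g_load %*% t(g)
        list(data = dat, latent = lat,
             voxels = tibble(roi = label, compartment = compartment,
                             high_sd = hi))
      })
    })
    vox <- bind_rows(purrr::map(blocks, "voxels")) %>%
      mutate(voxel = dplyr::row_number()) %>%
      select("voxel", "roi", "compartment", "high_sd")
    run <- list(
      participant_id = p,
      data = do.call(rbind, purrr::map(blocks, "data")),
      tr_seconds = cfg$tr_seconds,
      voxels = vox,
      latent = setNames(purrr::map(blocks, "latent"), specs$label)
    )
    structure(run, class = "bold_run")
  })
}

# 1-based TR index of the middle of a clip (convention shared with
# clip_pattern()).
clip_middle_tr <- function(onset_s, duration_s, tr_seconds) {
  pmax(1L, as.integer(round((onset_s + duration_s / 2) / tr_seconds)))
}

#' Ground-truth latent displacements per interval
#'
#' Recomputes, from the stored latent walks, the Euclidean distance travelled
#' by each region's latent context between the two clip midpoints of every
#' interval. This is the generator's ground truth against which recovery is
#' judged.
#'
#' @param runs List of `bold_run`s from [generate_bold()].
#' @param schedule The matching `clip_schedule`.
#' @return Tibble: `participant_id`, `roi`, `interval_id`, `displacement`.
#' @export
latent_displacement <- function(runs, schedule) {
  ints <- schedule$intervals
  clips <- schedule$clips
  mid <- clip_middle_tr(clips$onset_s, clips$duration_s, schedule$tr_seconds)
  purrr::map_dfr(runs, function(run) {
    purrr::imap_dfr(run$latent, function(lat, roi) {
      d <- vapply(seq_len(nrow(ints)), function(i) {
        a <- mid[ints$clip_a[i]]; b <- mid[ints$clip_b[i]]
        sqrt(sum((lat[b, ] - lat[a, ])^2))
      }, numeric(1))
      tibble(participant_id = run$participant_id, roi = roi,
             interval_id = ints$interval_id, displacement = d)
    })
  })
}

# Smooth story-level "content" process and per-clip feature vectors whose dot
# products decay with story-time separation.
content_features <- function(schedule, seed, k = 8L, smooth_sd = 40) {
  T_ <- schedule$n_trs
  with_seed(substream_seed(seed, 404), {
    proc <- gauss_smooth(matrix(rnorm(T_ * k), T_, k), smooth_sd)
    proc <- scale(proc)
    clip_noise <- matrix(rnorm(nrow(schedule$clips) * k, sd = 0.3),
                         ncol = k)
  })
  mid <- clip_middle_tr(schedule$clips$onset_s, schedule$clips$duration_s,
                        schedule$tr_seconds)
  feats <- proc[mid, , drop = FALSE] + clip_noise
  list(process = proc, features = feats)
}

#' Generate behavioral tables for a synthetic dataset
#'
#' Original participants' estimates follow
#' `intercept + gap_slope * true_gap + effect_size * drift + content_effect *
#' content + participant offset + noise`, floored at 0 and reported with 1 s
#' resolution; `drift` is the standardized latent displacement of the effect
#' region and `content` the standardized clip-content dissimilarity. Naive
#' estimates depend on the content term only. Event-boundary press times are
#' drawn with a rate proportional to the story-level contextual step size.
#' Confidence ratings (1-5) are drawn per clip with participant-specific
#' calibration, independent of accuracy.
#'
#' @param cfg A [synth_config()].
#' @param schedule The `clip_schedule`.
#' @param truth Displacement tibble from [latent_displacement()] (only the
#'   `effect_roi` rows are used). May be `NULL` when `effect_size = 0`.
#' @return List with tibbles `reports`, `clip_confidence`, `naive_reports`,
#'   `naive_clip_confidence`, `boundaries` and the per-interval
#'   `content_term`.
#' @export
generate_behavior <- function(cfg, schedule, truth = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  ints <- schedule$intervals
  n_int <- nrow(ints)
  cf <- content_features(schedule, cfg$seed)
  fa <- cf$features[ints$clip_a, , drop = FALSE]
  fb <- cf$features[ints$clip_b, , drop = FALSE]
  dotsim <- rowSums(fa * fb)
  content_term <- as.numeric(scale(-dotsim))  # dissimilarity direction

  if (cfg$effect_size != 0) {
    if (is.null(truth)) abort("truth displacements required when effect_size != 0")
    disp <- truth %>%
      filter(.data$roi == cfg$effect_roi) %>%
      group_by(.data$participant_id) %>%
      mutate(z_disp = as.numeric(scale(.data$displacement))) %>%
      ungroup()
  }

  make_reports <- function(n_subj, group, use_gap, use_drift, intercept,
                           seed_key) {
    purrr::map_dfr(seq_len(n_subj), function(p) {
      with_seed(substream_seed(cfg$seed, seed_key, p), {
        offset <- rnorm(1, sd = cfg$participant_sd_s)
        eps <- rnorm(n_int, sd = cfg$estimate_noise_sd_s)
        est <- intercept + offset + eps +
          cfg$content_effect * 60 * content_term
        if (use_gap) est <- est + cfg$gap_slope * ints$true_gap_s
        if (use_drift) {
          zd <- disp$z_disp[disp$participant_id == p][ints$interval_id]
          est <- est + cfg$effect_size * 60 * zd
        }
        tibble(participant_id = p, interval_id = ints$interval_id,
               estimate_s = pmax(0, round(est)),
               true_gap_s = ints$true_gap_s, group = group)
      })
    })
  }
  reports <- make_reports(cfg$n_participants, "original", use_gap = TRUE,
                          use_drift = cfg$effect_size != 0,
                          cfg$intercept_s, 505)
  naive_reports <- make_reports(cfg$n_naive, "naive", use_gap = FALSE,
                                use_drift = FALSE,
                                cfg$naive_intercept_s, 606)

  conf_table <- function(n_subj, seed_key) {
    n_clip <- nrow(schedule$clips)
    purrr::map_dfr(seq_len(n_subj), function(p) {
      with_seed(substream_seed(cfg$seed, seed_key, p), {
        calib <- rnorm(1, sd = 0.8)
        raw <- 3 + calib + rnorm(n_clip, sd = cfg$confidence_noise)
        tibble(participant_id = p, clip_id = schedule$clips$clip_id,
               confidence = pmin(5L, pmax(1L, as.integer(round(raw)))))
      })
    })
  }
  clip_confidence <- conf_table(cfg$n_participants, 707)
  naive_clip_confidence <- conf_table(cfg$n_naive, 708)

  # boundary presses: thinned Bernoulli per TR, rate tied to contextual step
  step <- c(0, sqrt(rowSums(diff(cf$process)^2)))
  step <- step / mean(step)
  lambda <- cfg$boundary_rate_per_min / 60 * step * schedule$tr_seconds
  boundaries <- purrr::map_dfr(seq_len(cfg$n_boundary_raters), function(r) {
    hit <- with_seed(substream_seed(cfg$seed, 809, r),
                     runif(length(lambda)) < lambda)
    tibble(rater = r,
           press_time_s = (which(hit) - 0.5) * schedule$tr_seconds)
  })

  list(reports = reports, clip_confidence = clip_confidence,
       naive_reports = naive_reports,
       naive_clip_confidence = naive_clip_confidence,
       boundaries = boundaries,
       content_term = tibble(interval_id = ints$interval_id,
                             content_term = content_term))
}

#' Generate a complete synthetic dataset
#'
#' Runs [generate_schedule()], [generate_bold()], [latent_displacement()] and
#' [generate_behavior()] under the config's master seed. Regeneration under
#' the same config is bit-identical.
#'
#' @param cfg A [synth_config()].
#' @param bold If `FALSE`, skip BOLD generation (behavioral-only datasets are
#'   much cheaper; drift displacements are still computed from the latent
#'   walks of the effect region only).
#' @return An object of class `synth_dataset`.
#' @export
synth_dataset <- function(cfg, bold = TRUE) {
  schedule <- generate_schedule(cfg)
  runs <- NULL
  truth <- NULL
  if (bold) {
    runs <- generate_bold(cfg, schedule)
    truth <- latent_displacement(runs, schedule)
  } else if (cfg$effect_size != 0) {
    # latent walks only, for the effect region, matching generate_bold seeds
    specs <- cfg$roi_specs
    idx <- match(cfg$effect_roi, specs$label)
    mid <- clip_middle_tr(schedule$clips$onset_s, schedule$clips$duration_s,
                          cfg$tr_seconds)
    ints <- schedule$intervals
    truth <- purrr::map_dfr(seq_len(cfg$n_participants), function(p) {
      lat <- with_seed(substream_seed(cfg$seed, 303, p, idx),
                       latent_walk(cfg$n_trs, specs$drift_rate[idx]))
      d <- vapply(seq_len(nrow(ints)), function(i) {
        sqrt(sum((lat[mid[ints$clip_b[i]], ] - lat[mid[ints$clip_a[i]], ])^2))
      }, numeric(1))
      tibble(participant_id = p, roi = cfg$effect_roi,
             interval_id = ints$interval_id, displacement = d)
    })
  }
  beh <- generate_behavior(cfg, schedule, truth)
  structure(
    c(list(config = cfg, schedule = schedule, runs = runs, truth = truth),
      beh),
    class = "synth_dataset"
  )
}
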