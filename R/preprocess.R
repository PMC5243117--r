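# Algorithmic BOLD preprocessing: despiking, Gaussian running-line high-pass
# filtering, nuisance residualization, ISC-based filter-cutoff selection,
# temporal smoothing.

#' High-pass filter specification
#'
#' Exposes the cutoff period and derives the Gaussian scale as
#' `sigma_s = cutoff_s / 2` (the convention used by FSL's running-line
#' filter, which reconciles a reported sigma of 240 s with a selected cutoff
#' of 480 s).
#'
#' @param cutoff_s Cutoff period in seconds.
#' @return An object of class `filter_spec` with fields `cutoff_s`,
#'   `sigma_s`.
#' @export
filter_spec <- function(cutoff_s) {
  if (cutoff_s <= 0) abort("cutoff must be positive")
  structure(list(cutoff_s = cutoff_s, sigma_s = cutoff_s / 2),
            class = "filter_spec")
}

#' Despike a time series
#'
#' Points deviating from the series mean by more than 5 times the
#' inter-quartile range are removed and replaced by cubic interpolation over
#' the surviving points; flagged points at the edges take the nearest
#' surviving value.
#'
#' @param x Numeric vector (length >= 4).
#' @param iqr_mult Flagging multiple of the IQR.
#' @return Despiked vector, same length.
#' @export
despike <- function(x, iqr_mult = 5) {
  if (length(x) < 4) abort("series too short to despike")
  iqr <- IQR(x)
  bad <- abs(x - mean(x)) > iqr_mult * iqr
  if (!any(bad)) return(x)
  if (mean(bad) > 0.5) abort("more than 50% of points flagged: pathological series")
  t_all <- seq_along(x)
  good <- !bad
  sp <- spline(t_all[good], x[good], xout = t_all[bad], method = "fmm")$y
  out <- x
  out[bad] <- sp
  # edge spikes: nearest surviving neighbour, not cubic extrapolation
  first_good <- min(t_all[good]); last_good <- max(t_all[good])
  out[t_all < first_good] <- x[first_good]
  out[t_all > last_good] <- x[last_good]
  out
}

#' Despike every voxel of a run
#'
#' @param run A `bold_run`.
#' @param iqr_mult Flagging multiple of the IQR.
#' @return The run with despiked data.
#' @export
despike_run <- function(run, iqr_mult = 5) {
  run$data <- t(apply(run$data, 1, despike, iqr_mult = iqr_mult))
  run
}

# Dense smoother matrix for the Gaussian-weighted running-line fit: row t
# holds the weights giving the local linear fit evaluated at t. Depends only
# on (T, sigma in samples), so it is cached per call site and applied to all
# voxels at once.
.runline_cache <- new.env(parent = emptyenv())

runline_smoother <- function(n, sigma_pts) {
  key <- sprintf("%d_%.6f", n, sigma_pts)
  hit <- .runline_cache[[key]]
  if (!is.null(hit)) return(hit)
  t_idx <- seq_len(n)
  H <- matrix(0, n, n)
  for (t in t_idx) {
    d <- t_idx - t
    w <- exp(-d^2 / (2 * sigma_pts^2))
    s0 <- sum(w); s1 <- sum(w * d); s2 <- sum(w * d^2)
    denom <- s0 * s2 - s1^2
    H[t, ] <- (s2 * w - s1 * (w * d)) / denom
  }
  if (length(.runline_cache) > 8) rm(list = ls(.runline_cache),
                                     envir = .runline_cache)
  .runline_cache[[key]] <- H
  H
}

#' Gaussian-weighted running-line high-pass filter
#'
#' At each time point the value of a straight line fitted by least squares
#' under Gaussian weights of scale `sigma_s` is subtracted; the series mean
#' is re-added so the output keeps the input mean. Operates on a vector or on
#' the rows of a voxel x time matrix.
#'
#' @param x Numeric vector or matrix (voxels in rows).
#' @param tr_seconds Sampling period.
#' @param spec A [filter_spec()] (or a cutoff in seconds).
#' @return Filtered series, same shape.
#' @export
highpass <- function(x, tr_seconds, spec) {
  if (!inherits(spec, "filter_spec")) spec <- filter_spec(spec)
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  if (spec$cutoff_s >= n * tr_seconds) {
    warn("cutoff not shorter than run duration; filtering anyway")
  }
  H <- runline_smoother(n, spec$sigma_s / tr_seconds)
  low <- x %*% t(H)
  out <- x - low + rowMeans(x)
  if (vec) drop(out) else out
}

#' @rdname highpass
#' @param run A `bold_run`.
#' @export
highpass_run <- function(run, spec) {
  run$data <- highpass(run$data, run$tr_seconds, spec)
  run
}

#' Project nuisance signals out of every voxel
#'
#' Regresses every voxel on three nuisance regressors -- the mean time course
#' of the top-1% highest-SD voxels, the mean CSF signal and the mean white
#' matter signal -- plus an intercept, and returns residuals with the voxel
#' mean restored. Intended to run on high-pass-filtered data.
#'
#' @param run A `bold_run` whose `voxels` table labels compartments `csf`
#'   and `white`.
#' @param high_sd_fraction Fraction of voxels defining the high-SD pool
#'   (default 0.01, computed from the run itself).
#' @return The run with residualized data; the regressors are attached as
#'   attribute `"nuisance"`.
#' @export
nuisance_residualize <- function(run, high_sd_fraction = 0.01) {
  vox <- run$voxels
  for (comp in c("csf", "white")) {
    if (!any(vox$compartment == comp)) {
      abort(sprintf("empty compartment mask: %s", comp))
    }
  }
  X <- run$data
  sds <- apply(X, 1, sd)
  n_hi <- max(1L, ceiling(high_sd_fraction * nrow(X)))
  hi_idx <- order(sds, decreasing = TRUE)[seq_len(n_hi)]
  reg <- cbind(
    high_sd = colMeans(X[hi_idx, , drop = FALSE]),
    csf = colMeans(X[vox$compartment == "csf", , drop = FALSE]),
    wm = colMeans(X[vox$compartment == "white", , drop = FALSE])
  )
  mm <- cbind(1, reg)
  fit <- lm.fit(mm, t(X))
  run$data <- t(fit$residuals) + rowMeans(X)
  attr(run, "nuisance") <- reg
  run
}

roi_mean_course <- function(run, roi) {
  keep <- run$voxels$voxel[run$voxels$roi == roi]
  if (length(keep) == 0) abort(sprintf("no voxels in roi '%s'", roi))
  colMeans(run$data[keep, , drop = FALSE])
}

#' Inter-subject correlation of an ROI's mean time course
#'
#' For each participant, the Pearson correlation between their ROI-mean time
#' course and the average ROI-mean time course of all other participants.
#'
#' @param runs List of `bold_run`s.
#' @param roi ROI label.
#' @return Tibble: `participant_id`, `isc` (`NA`, with a warning, for a
#'   participant with a constant time course).
#' @export
isc <- function(runs, roi) {
  if (length(runs) < 3) abort("need at least 3 participants")
  courses <- vapply(runs, roi_mean_course, numeric(ncol(runs[[1]]$data)),
                    roi = roi)
  tot <- rowSums(courses)
  vals <- vapply(seq_along(runs), function(i) {
    own <- courses[, i]
    ref <- (tot - own) / (length(runs) - 1)
    if (sd(own) == 0 || sd(ref) == 0) return(NA_real_)
    cor(own, ref)
  }, numeric(1))
  if (anyNA(vals)) warn("constant time course: ISC undefined for some participant(s)")
  tibble(participant_id = purrr::map_dbl(runs, "participant_id"), isc = vals)
}

#' Select the gentlest admissible high-pass cutoff
#'
#' For each candidate cutoff the runs are high-pass filtered, residualized
#' and ISC is computed per region; the longest cutoff for which every
#' designated grey-matter ROI's ISC significantly exceeds the CSF ISC
#' (paired one-tailed t-test, `alpha`) is selected. If none qualifies the
#' shortest candidate is returned with a warning.
#'
#' @param runs List of `bold_run`s.
#' @param grey_rois Character vector of grey-matter ROI labels.
#' @param csf_roi CSF ROI label.
#' @param candidate_cutoffs Candidate cutoffs in seconds, ascending.
#' @param alpha Test level.
#' @return A [filter_spec()] with the ISC table attached as attribute
#'   `"isc_table"`.
#' @export
select_cutoff <- function(runs, grey_rois, csf_roi = "csf",
                          candidate_cutoffs = c(140, 240, 300, 400, 480,
                                                600, 720),
                          alpha = 0.05) {
  cands <- sort(candidate_cutoffs)
  tab <- purrr::map_dfr(cands, function(cut) {
    proc <- purrr::map(runs, function(r) {
      nuisance_residualize(highpass_run(r, filter_spec(cut)))
    })
    purrr::map_dfr(c(grey_rois, csf_roi), function(roi) {
      isc(proc, roi) %>% mutate(roi = roi, cutoff_s = cut)
    })
  })
  qualifies <- vapply(cands, function(cut) {
    sub <- tab %>% filter(.data$cutoff_s == cut)
    csf_vals <- sub$isc[sub$roi == csf_roi]
    all(vapply(grey_rois, function(g) {
      gv <- sub$isc[sub$roi == g]
      ok <- stats::complete.cases(cbind(gv, csf_vals))
      if (sum(ok) < 2 || sd(gv[ok] - csf_vals[ok]) == 0) return(FALSE)
      t.test(gv[ok], csf_vals[ok], paired = TRUE,
             alternative = "greater")$p.value < alpha
    }, logical(1)))
  }, logical(1))
  if (any(qualifies)) {
    chosen <- max(cands[qualifies])
  } else {
    warn("no cutoff qualifies; returning shortest candidate")
    chosen <- min(cands)
  }
  spec <- filter_spec(chosen)
  attr(spec, "isc_table") <- tab
  spec
}

#' Centered moving-average smoothing
#'
#' @param x Numeric vector or voxel x time matrix.
#' @param width Odd window width in samples; edges use shrinking windows.
#' @return Smoothed series, same shape.
#' @export
smooth_window <- function(x, width = 5) {
  if (width %% 2 != 1) abort("width must be odd")
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  if (width > n) abort("width exceeds series length")
  half <- (width - 1) / 2
  k <- rep(1, width)
  sm <- t(apply(x, 1, function(row) {
    padded <- c(rep(0, half), row, rep(0, half))
    num <- as.numeric(stats::filter(padded, k, sides = 2))[(half + 1):(half + n)]
    cnt <- as.numeric(stats::filter(c(rep(0, half), rep(1, n), rep(0, half)),
                                    k, sides = 2))[(half + 1):(half + n)]
    num / cnt
  }))
  if (vec) drop(sm) else sm
}

#' @rdname smooth_window
#' @param run A `bold_run`.
#' @export
smooth_run <- function(run, width = 5) {
  run$data <- smooth_window(run$data, width)
  run
}
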