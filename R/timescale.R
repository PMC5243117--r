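# Slowness of signal change per region: autocorrelation FWHM computed
# multivariately (pattern autocorrelation), with ROI size regressed out, and
# univariately (voxel autocorrelation), plus region rankings and signed-rank
# comparisons.

acf_fwhm <- function(lags, acf_vals) {
  m <- max(acf_vals, na.rm = TRUE)
  sum(acf_vals >= m / 2, na.rm = TRUE)
}

new_acf_profile <- function(lags, mean_acf, method) {
  structure(list(lags = lags, mean_acf = mean_acf,
                 fwhm_trs = acf_fwhm(lags, mean_acf), method = method),
            class = "acf_profile")
}

#' @export
print.acf_profile <- function(x, ...) {
  cat(sprintf("<acf_profile> method %s | lags %d..%d | FWHM = %d TRs\n",
              x$method, min(x$lags), max(x$lags), x$fwhm_trs))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.acf_profile <- function(x, ...) {
  tibble(lag = x$lags, acf = x$mean_acf, method = x$method)
}

#' Multivariate pattern autocorrelation profile
#'
#' Correlates the multivoxel pattern at every TR with the pattern at every
#' other TR, averages the curves across reference TRs aligned at lag 0
#' (shrinking sample at large lags, no padding), and takes the FWHM: the
#' number of lags over the evaluated symmetric range at which the mean
#' autocorrelation is at or above half its maximum. The evaluated range is
#' capped at +/- T/4.
#'
#' @param run A `bold_run` (smooth first with [smooth_run()] for the
#'   denoised variant).
#' @param roi ROI label (>= `min_voxels` voxels).
#' @param max_lag Largest |lag| evaluated; default `floor(T/4)`.
#' @param min_voxels Minimum ROI size.
#' @return An `acf_profile` (fields `lags`, `mean_acf`, `fwhm_trs`,
#'   `method`).
#' @export
pattern_acf <- function(run, roi, max_lag = NULL, min_voxels = 10) {
  vox <- roi_voxel_idx(run, roi)
  if (length(vox) < min_voxels) {
    abort(sprintf("roi '%s' has fewer than %d voxels", roi, min_voxels),
          class = "contextdrift_small_roi")
  }
  if (length(vox) == 1) {
    # a one-voxel "pattern" degenerates to the voxel time course; both
    # methods must agree there
    prof <- voxel_acf(run, roi, max_lag = max_lag, min_voxels = min_voxels)
    prof$method <- "multivariate"
    return(prof)
  }
  X <- run$data[vox, , drop = FALSE]
  T_ <- ncol(X)
  max_lag <- max_lag %||% floor(T_ / 4)
  C <- suppressWarnings(cor(X))
  lags <- -max_lag:max_lag
  mean_acf <- vapply(lags, function(k) {
    if (k == 0) return(1)
    i <- seq_len(T_ - abs(k))
    mean(C[cbind(i, i + abs(k))], na.rm = TRUE)
  }, numeric(1))
  new_acf_profile(lags, mean_acf, "multivariate")
}

#' Univariate voxel autocorrelation profile
#'
#' Autocorrelation of each voxel's time course at all evaluated lags,
#' averaged across the ROI's voxels (constant voxels are excluded with a
#' message); FWHM as in [pattern_acf()].
#'
#' @inheritParams pattern_acf
#' @return An `acf_profile` with `method = "univariate"`.
#' @export
voxel_acf <- function(run, roi, max_lag = NULL, min_voxels = 10) {
  vox <- roi_voxel_idx(run, roi)
  if (length(vox) < min_voxels) {
    abort(sprintf("roi '%s' has fewer than %d voxels", roi, min_voxels),
          class = "contextdrift_small_roi")
  }
  X <- run$data[vox, , drop = FALSE]
  T_ <- ncol(X)
  max_lag <- max_lag %||% floor(T_ / 4)
  keep <- apply(X, 1, sd) > 0
  if (!all(keep)) {
    inform(sprintf("excluding %d constant voxel(s) from the acf average",
                   sum(!keep)))
  }
  X <- X[keep, , drop = FALSE]
  curves <- apply(X, 1, function(v) {
    stats::acf(v, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  })
  pos <- rowMeans(curves)  # lags 0..max_lag
  lags <- -max_lag:max_lag
  mean_acf <- c(rev(pos[-1]), pos)
  new_acf_profile(lags, mean_acf, "univariate")
}

#' FWHM table over regions and participants
#'
#' @param runs List of `bold_run`s (already smoothed if desired).
#' @param rois Region labels.
#' @param method `"multivariate"` or `"univariate"`.
#' @param max_lag Passed through.
#' @return Tibble: `roi`, `participant_id`, `method`, `fwhm_trs`
#'   (`NA` for skipped small regions).
#' @export
fwhm_table <- function(runs, rois, method = c("multivariate", "univariate"),
                       max_lag = NULL) {
  method <- match.arg(method)
  fn <- if (method == "multivariate") pattern_acf else voxel_acf
  purrr::map_dfr(runs, function(run) {
    purrr::map_dfr(rois, function(roi) {
      f <- tryCatch(fn(run, roi, max_lag = max_lag)$fwhm_trs,
                    contextdrift_small_roi = function(e) NA_integer_)
      tibble(roi = roi, participant_id = run$participant_id,
             method = method, fwhm_trs = f)
    })
  })
}

#' Regress ROI size out of FWHM values
#'
#' Per participant, ordinary least squares of the FWHM vector on the ROI
#' size vector; residuals are returned (centered FWHM when sizes are
#' constant).
#'
#' @param fwhm_tbl Tibble: `roi`, `participant_id`, `fwhm_trs`.
#' @param sizes Tibble: `roi`, `n_voxels`.
#' @return `fwhm_tbl` with column `fwhm_resid`.
#' @export
regress_out_size <- function(fwhm_tbl, sizes) {
  if (dplyr::n_distinct(fwhm_tbl$roi) < 3) abort("need at least 3 regions")
  fwhm_tbl %>%
    left_join(sizes, by = "roi") %>%
    group_by(.data$participant_id) %>%
    dplyr::group_modify(function(d, key) {
      if (sd(d$n_voxels) == 0) {
        d$fwhm_resid <- d$fwhm_trs - mean(d$fwhm_trs)
      } else {
        d$fwhm_resid <- resid(lm(fwhm_trs ~ n_voxels, data = d))
      }
      d
    }) %>%
    ungroup()
}

#' Compare two regions' FWHM values and rank regions
#'
#' Right-tailed paired Wilcoxon signed-rank test of region `roi_a` against
#' `roi_b` across participants, plus the ranking of every region's mean
#' FWHM (1 = slowest).
#'
#' @param fwhm_tbl Tibble: `roi`, `participant_id`, and a value column.
#' @param roi_a,roi_b Region labels (`roi_a` hypothesized slower).
#' @param value Name of the value column (default `fwhm_trs`).
#' @param alternative Passed to [stats::wilcox.test()].
#' @return List: `p`, `statistic`, `rankings` tibble
#'   (`roi`, `mean_value`, `rank`).
#' @export
compare_regions <- function(fwhm_tbl, roi_a, roi_b, value = "fwhm_trs",
                            alternative = "greater") {
  wide <- fwhm_tbl %>%
    select("roi", "participant_id", value = all_of(value)) %>%
    tidyr::pivot_wider(names_from = "roi", values_from = "value")
  a <- wide[[roi_a]]; b <- wide[[roi_b]]
  ok <- complete.cases(cbind(a, b))
  d <- a[ok] - b[ok]
  if (all(d == 0)) {
    warn("all paired differences tied: p undefined")
    wt <- list(p.value = NA_real_, statistic = NA_real_)
  } else {
    wt <- suppressWarnings(
      wilcox.test(a[ok], b[ok], paired = TRUE, alternative = alternative)
    )
  }
  rankings <- fwhm_tbl %>%
    group_by(.data$roi) %>%
    summarise(mean_value = mean(.data[[value]], na.rm = TRUE),
              .groups = "drop") %>%
    mutate(rank = rank(-.data$mean_value, ties.method = "min")) %>%
    arrange(.data$rank)
  list(p = wt$p.value, statistic = unname(wt$statistic),
       rankings = rankings)
}
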