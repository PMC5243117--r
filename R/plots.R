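# ggplot2 views of the main result objects.

#' @exportS3Method ggplot2::autoplot
autoplot.acf_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag, y = .data$acf)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_hline(yintercept = max(df$acf) / 2, linetype = "dashed") +
    ggplot2::labs(
      x = "lag (TRs)", y = "mean autocorrelation",
      title = sprintf("%s autocorrelation, FWHM = %d TRs",
                      object$method, object$fwhm_trs)
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.null_ensemble <- function(object, bins = 50, ...) {
  df <- tibble(null = object$nulls)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", color = "white") +
    ggplot2::geom_vline(xintercept = object$empirical, color = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(
      x = "null correlation (Fisher z)", y = "count",
      title = sprintf("empirical vs %d surrogate correlations (z = %.2f)",
                      length(object$nulls), object$z)
    ) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.distance_series <- function(object, ...) {
  df <- tibble(center_tr = object$center_tr, distance = object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$center_tr, y = .data$distance)) +
    ggplot2::geom_line(color = "darkorange") +
    ggplot2::labs(
      x = "window center (TR)",
      y = sprintf("pattern distance at lag %d TRs", object$lag_trs),
      title = "lagged pattern-distance time course"
    ) +
    ggplot2::theme_minimal()
}

#' Mean duration estimates by true gap
#'
#' One point per participant and gap, with bars at the grand means.
#'
#' @param reports Reports tibble.
#' @param schedule A `clip_schedule`.
#' @return A ggplot object.
#' @export
plot_gap_means <- function(reports, schedule) {
  pm <- per_participant_gap_means(reports, schedule) %>%
    mutate(gap = factor(.data$true_gap_s / 60,
                        labels = paste(sort(unique(.data$true_gap_s)) / 60,
                                       "min")),
           est_min = .data$mean_est_s / 60)
  ggplot2::ggplot(pm, ggplot2::aes(x = .data$gap, y = .data$est_min)) +
    ggplot2::stat_summary(fun = mean, geom = "col", fill = "steelblue",
                          alpha = 0.5, width = 0.6) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::labs(x = "true gap", y = "mean duration estimate (min)") +
    ggplot2::theme_minimal()
}

#' Heatmap of one axial slice of a statistic map
#'
#' @param map A `stat_map` (3D array).
#' @param z Slice index (default middle).
#' @return A ggplot object.
#' @export
plot_stat_map_slice <- function(map, z = NULL) {
  dims <- dim(map)
  z <- z %||% ceiling(dims[3] / 2)
  df <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]))
  df$value <- as.numeric(map[, , z])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("statistic map, slice z = %d", z)) +
    ggplot2::theme_minimal()
}
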