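# Hierarchical regression of duration estimates on neural pattern distance,
# controlling for naive estimates, with crossed participant and interval
# random effects, a Box-Cox response transform and Wald confidence
# intervals.

#' Box-Cox exponent by profile likelihood
#'
#' Maximizes the Box-Cox profile likelihood of a fixed-effects-only linear
#' model over a grid on \[-2, 2\] with step 0.01.
#'
#' @param y Positive response vector. Zeros are allowed only with
#'   `shift > 0` (shift-by-epsilon option; the shift used is recorded in the
#'   result's attributes).
#' @param x Optional fixed-effects design matrix or data frame of
#'   covariates; default intercept-only.
#' @param shift Amount added to `y` before transforming (default 0).
#' @return The maximizing lambda, with attributes `shift` and `grid_step`.
#' @export
boxcox_lambda <- function(y, x = NULL, shift = 0) {
  y <- y + shift
  if (any(y <= 0)) {
    abort("response contains nonpositive values; use the shift option")
  }
  df <- data.frame(.y = y)
  form <- .y ~ 1
  if (!is.null(x)) {
    x <- as.data.frame(x)
    df <- cbind(df, x)
    form <- stats::reformulate(names(x), response = ".y")
  }
  fit0 <- do.call(stats::lm, list(formula = form, data = df,
                                  x = TRUE, y = TRUE))
  bc <- MASS::boxcox(fit0, lambda = seq(-2, 2, 0.01), plotit = FALSE)
  lam <- bc$x[which.max(bc$y)]
  structure(lam, shift = shift, grid_step = 0.01)
}

#' Box-Cox power transform
#'
#' @param y Positive values.
#' @param lambda Exponent; `(y^lambda - 1)/lambda`, or `log(y)` at
#'   `lambda = 0`.
#' @param shift Added to `y` first.
#' @return Transformed vector.
#' @export
boxcox_transform <- function(y, lambda, shift = 0) {
  y <- y + shift
  if (any(y <= 0)) abort("nonpositive values cannot be power-transformed")
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

#' Fit the crossed-random-effects duration model
#'
#' Fits `y ~ 1 + naive + distance + (1 + naive + distance | subject) +
#' (1 + distance | interval)` where `y` is the Box-Cox-transformed duration
#' estimate, `naive` the naive group's per-interval mean estimate and
#' `distance` the neural pattern distance (both covariates standardized
#' over the analysis set). The naive slope varies by subject only, since
#' naive means do not vary by subject. If the maximal fit fails to converge
#' or its random-effects covariance is singular, the random-effects
#' structure is simplified stepwise (correlations dropped, then slopes,
#' then intercepts-only); the ladder of attempts is recorded.
#'
#' @param data Tibble with columns `estimate_s`, `naive`, `distance`,
#'   `subject`, `interval`.
#' @param include_naive Include the naive covariate (the model variant
#'   without it is also reported in practice).
#' @param lambda Box-Cox exponent; `NULL` picks it by [boxcox_lambda()] on
#'   the fixed-effects-only model.
#' @param shift Response shift for zeros.
#' @return Object of class `drift_lmm`: list with `fit` (the lmer fit),
#'   `beta`, `wald_ci`, `lambda`, `formula_used`, `ladder`, `converged`.
#' @export
fit_mixed <- function(data, include_naive = TRUE, lambda = NULL,
                      shift = NULL) {
  need <- c("estimate_s", "distance", "subject", "interval")
  if (include_naive) need <- c(need, "naive")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  if (dplyr::n_distinct(data$subject) < 2 ||
      dplyr::n_distinct(data$interval) < 2) {
    abort("need at least 2 subjects and 2 intervals")
  }
  if (is.null(shift)) shift <- if (any(data$estimate_s <= 0)) 1 else 0
  covars <- if (include_naive) c("naive", "distance") else "distance"
  if (is.null(lambda)) {
    lambda <- boxcox_lambda(data$estimate_s, data[covars], shift = shift)
  }
  d <- data %>%
    mutate(y = boxcox_transform(.data$estimate_s, lambda, shift),
           distance = as.numeric(scale(.data$distance)),
           subject = factor(.data$subject),
           interval = factor(.data$interval))
  if (include_naive) d <- d %>% mutate(naive = as.numeric(scale(.data$naive)))

  fixed <- if (include_naive) "y ~ 1 + naive + distance" else "y ~ 1 + distance"
  res <- if (include_naive) {
    c("(1 + naive + distance | subject) + (1 + distance | interval)",
      "(1 + naive + distance || subject) + (1 + distance || interval)",
      "(1 + distance || subject) + (1 + distance || interval)",
      "(1 | subject) + (1 | interval)")
  } else {
    c("(1 + distance | subject) + (1 + distance | interval)",
      "(1 + distance || subject) + (1 + distance || interval)",
      "(1 | subject) + (1 | interval)")
  }
  ladder <- character(0)
  fit <- NULL
  used <- NA_character_
  for (re in res) {
    form <- stats::as.formula(paste(fixed, "+", re))
    cand <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(form, data = d,
                   control = lme4::lmerControl(calc.derivs = FALSE))
      )),
      error = function(e) NULL
    )
    status <- if (is.null(cand)) {
      "error"
    } else if (lme4::isSingular(cand, tol = 1e-4)) {
      "singular"
    } else {
      "ok"
    }
    ladder <- c(ladder, paste(re, "->", status))
    if (status == "ok") {
      fit <- cand
      used <- re
      break
    }
    if (status == "singular" && is.null(fit)) {
      # keep the first singular fit as a fallback if nothing converges cleanly
      fit <- cand
      used <- re
    }
  }
  if (is.null(fit)) {
    abort(paste0("mixed model failed to converge; ladder: ",
                 paste(ladder, collapse = "; ")))
  }
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  ci <- cbind(lo = beta - qnorm(0.975) * se, hi = beta + qnorm(0.975) * se)
  structure(list(fit = fit, beta = beta, se = se, wald_ci = ci,
                 lambda = as.numeric(lambda), shift = shift,
                 include_naive = include_naive, formula_used = used,
                 ladder = ladder,
                 converged = grepl("-> ok$", utils::tail(ladder, 1))),
            class = "drift_lmm")
}

#' @export
print.drift_lmm <- function(x, ...) {
  cat(sprintf("<drift_lmm> lambda = %.2f, RE structure: %s\n",
              x$lambda, x$formula_used))
  print(tidy(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.drift_lmm <- function(x, ...) {
  tibble(term = names(x$beta), estimate = unname(x$beta),
         std_error = unname(x$se),
         ci_lo = unname(x$wald_ci[, "lo"]), ci_hi = unname(x$wald_ci[, "hi"]),
         excludes_zero = x$wald_ci[, "lo"] > 0 | x$wald_ci[, "hi"] < 0)
}

#' @exportS3Method generics::glance
glance.drift_lmm <- function(x, ...) {
  ll <- stats::logLik(x$fit)
  tibble(lambda = x$lambda, re_structure = x$formula_used,
         converged = x$converged, sigma = stats::sigma(x$fit),
         logLik = as.numeric(ll), df = attr(ll, "df"),
         nobs = stats::nobs(x$fit))
}

#' Fixed-effect table over regions
#'
#' Collects fixed effects and Wald CIs from per-region fits, flagging CIs
#' that exclude zero; typically called with fits for the model with and
#' without the naive covariate.
#'
#' @param fits Named list of `drift_lmm` objects (names = region labels).
#' @param variant Label stored in the `variant` column.
#' @return Tibble: `roi`, `term`, `estimate`, `ci_lo`, `ci_hi`,
#'   `excludes_zero`, `variant`.
#' @export
report_fixed_effects <- function(fits, variant = "with_naive") {
  if (length(fits) == 0) {
    return(tibble(roi = character(), term = character(),
                  estimate = numeric(), ci_lo = numeric(),
                  ci_hi = numeric(), excludes_zero = logical(),
                  variant = character()))
  }
  purrr::imap_dfr(fits, function(f, nm) {
    tidy(f) %>%
      mutate(roi = nm, variant = variant) %>%
      select("roi", "term", "estimate", "ci_lo", "ci_hi",
             "excludes_zero", "variant")
  })
}

#' Assemble the modeling table for one region
#'
#' Joins original duration estimates, the naive group's per-interval mean
#' estimates ("naive participants could not be matched, so their estimates
#' are group-averaged") and per-participant pattern distances into the long
#' table [fit_mixed()] expects.
#'
#' @param reports Original reports tibble.
#' @param naive_reports Naive group reports tibble.
#' @param dist_table Tibble `participant_id`, `interval_id`, `distance`.
#' @param retained Optional retained-interval tibble from
#'   [confidence_filter()].
#' @return Tibble: `subject`, `interval`, `estimate_s`, `naive`, `distance`.
#' @export
mixed_model_table <- function(reports, naive_reports, dist_table,
                              retained = NULL) {
  naive_mean <- naive_reports %>%
    group_by(.data$interval_id) %>%
    summarise(naive = mean(.data$estimate_s), .groups = "drop")
  df <- reports %>%
    dplyr::inner_join(dist_table, by = c("participant_id", "interval_id")) %>%
    dplyr::inner_join(naive_mean, by = "interval_id")
  if (!is.null(retained)) {
    df <- df %>%
      dplyr::semi_join(retained %>% filter(.data$retained),
                       by = c("participant_id", "interval_id"))
  }
  df %>%
    filter(!is.na(.data$distance)) %>%
    mutate(subject = .data$participant_id, interval = .data$interval_id) %>%
    select("subject", "interval", "estimate_s", "naive", "distance")
}
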