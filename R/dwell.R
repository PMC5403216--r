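#' Left-truncated exponential maximum likelihood fit
#'
#' Tracks shorter than the acceptance threshold are discarded, so observed
#' durations follow a left-truncated exponential with truncation point L.
#' The continuous MLE of the mean-beyond-truncation is the closed form
#' `tau = mean(durations) - L`. Because durations are quantized to the frame
#' grid, the continuous estimate understates the underlying continuous-time
#' constant by about half an interval; with `grid_correction = TRUE` the
#' fit instead uses the MLE under the discretized (geometric) model,
#' `tau = delta / log(1 + delta / (mean - L))` with `delta` the interval
#' time, which removes the quantization bias.
#'
#' @param sample A [track_duration_sample()].
#' @param grid_correction Correct for frame-grid quantization (default
#'   FALSE: the plain continuous closed form).
#' @return An object of class `exponential_fit` with elements `tau`, `se`,
#'   `ci95`, `log_likelihood`, `n`, `truncation_point`, `tau_continuous`,
#'   `tau_grid`, `method`.
#' @export
#' @examples
#' s <- track_duration_sample(c(3, 4, 8), truncation_point = 2,
#'                            settings = acquisition_settings(0.5, 1))
#' fit_truncated_exponential(s)$tau  # 3
fit_truncated_exponential <- function(sample, grid_correction = FALSE) {
  stopifnot(inherits(sample, "track_duration_sample"))
  x <- sample$durations
  L <- sample$truncation_point
  n <- length(x)
  if (n < 1L) stop_invalid("empty duration sample")
  if (any(x < L)) stop_invalid("all durations must be >= the truncation point")
  m <- mean(x) - L
  if (m <= 0) stop_invalid("degenerate sample: mean equals the truncation ",
                           "point, no information beyond L")
  delta <- sample$settings$interval_time
  tau_grid <- delta / log1p(delta / m)
  tau <- if (grid_correction) tau_grid else m
  # delta-method SE: the continuous estimate has SE m/sqrt(n); the grid
  # estimate rescales it by d tau_grid / d m = tau_grid^2 / (m (m + delta))
  se_m <- m / sqrt(n)
  se <- if (grid_correction) {
    tau_grid^2 / (m * (m + delta)) * se_m
  } else se_m
  log_likelihood <- if (grid_correction) {
    j <- round((x - L) / delta)
    q <- exp(-delta / tau_grid)
    sum(log(1 - q) + j * log(q))
  } else {
    -n * log(m) - sum(x - L) / m
  }
  structure(
    list(tau = tau, se = se, ci95 = tau + c(-1, 1) * 1.96 * se,
         log_likelihood = log_likelihood, n = n,
         truncation_point = L, interval_time = delta,
         tau_continuous = m, tau_grid = tau_grid,
         method = if (grid_correction) "grid" else "continuous"),
    class = "exponential_fit"
  )
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf("Truncated-exponential fit (%s): tau = %.3g s (SE %.2g), n = %d\n",
              x$method, x$tau, x$se, x$n))
  invisible(x)
}

#' Photobleaching calibration from a stable-binder control
#'
#' For a binder whose unbinding is negligible on the experimental timescale
#' (LacI on an operator array), the fitted track-duration constant equals
#' the effective bleach time at the control's acquisition settings. The
#' constant-exposure bleaching time is recovered by undoing the duty-cycle
#' scaling, `T_constant = tau * exposure / interval`, and can then be
#' rescaled to any other protocol with [bleach_time_at()].
#'
#' @param control A [track_duration_sample()] from a stable binder.
#' @param grid_correction Passed to [fit_truncated_exponential()]
#'   (default TRUE).
#' @return An object of class `bleach_calibration`: `T_constant`, `fit`,
#'   `control` (retained for bootstrap resampling), `grid_correction`.
#' @export
calibrate_bleach <- function(control, grid_correction = TRUE) {
  fit <- fit_truncated_exponential(control, grid_correction = grid_correction)
  st <- control$settings
  structure(
    list(T_constant = fit$tau * st$exposure_time / st$interval_time,
         fit = fit, control = control, grid_correction = grid_correction),
    class = "bleach_calibration"
  )
}

#' @export
print.bleach_calibration <- function(x, ...) {
  cat(sprintf("Bleach calibration: T_constant = %.3g s (from n = %d control tracks)\n",
              x$T_constant, x$fit$n))
  invisible(x)
}

#' Effective bleach time under given acquisition settings
#'
#' @param calibration A [calibrate_bleach()] result (or a plain
#'   constant-exposure bleach time in seconds).
#' @param settings An [acquisition_settings()] object.
#' @return Bleach time in seconds, scaled by `interval_time/exposure_time`.
#' @export
bleach_time_at <- function(calibration, settings) {
  t_constant <- if (inherits(calibration, "bleach_calibration")) {
    calibration$T_constant
  } else calibration
  bleach_time_scaled(t_constant, settings)
}

#' Photobleaching correction of a track-duration constant
#'
#' Track durations end through either unbinding or bleaching, so the rates
#' add: `1/T_track = 1/T_bound + 1/T_bleach`. Inverting gives
#' `T_bound = T_track * T_bleach / (T_bleach - T_track)`.
#'
#' @param t_track Fitted track-duration time constant, seconds.
#' @param t_bleach Effective bleach time at the same settings, seconds.
#' @return Corrected bound time in seconds.
#' @export
#' @examples
#' correct_bound_time(5, 10)   # 10
#' correct_bound_time(10, 30)  # 15
correct_bound_time <- function(t_track, t_bleach) {
  check_positive(t_track, "t_track")
  check_positive(t_bleach, "t_bleach")
  if (t_track >= t_bleach) {
    stop_invalid("uninformative estimate: the track time (", signif(t_track, 4),
                 " s) is not below the bleach time (", signif(t_bleach, 4),
                 " s), so the bound time is not identifiable")
  }
  t_track * t_bleach / (t_bleach - t_track)
}

#' Inverse-variance weighted average of bound-time estimates
#'
#' Final bound times are combined across acquisition days/intervals as a
#' weighted average. With standard errors available the weights are inverse
#' variances and the combined SE is `1/sqrt(sum(w))`; without them the
#' average falls back to sample-size weights (with a warning).
#'
#' @param estimates List of `bound_time_estimate` objects (or any lists with
#'   `T_bound`, `se`, `n`).
#' @return A list of class `bound_time_estimate` with the combined
#'   `T_bound`, `se`, `ci95`, total `n`, and the `inputs` retained.
#' @export
weighted_average <- function(estimates) {
  if (inherits(estimates, "bound_time_estimate")) estimates <- list(estimates)
  if (length(estimates) == 0L) stop_invalid("need at least one estimate")
  if (length(estimates) == 1L) return(estimates[[1L]])
  vals <- vapply(estimates, `[[`, numeric(1), "T_bound")
  ses <- vapply(estimates, function(e) {
    if (is.null(e$se) || is.na(e$se)) NA_real_ else e$se
  }, numeric(1))
  ns <- vapply(estimates, function(e) {
    if (is.null(e$n)) NA_real_ else as.numeric(e$n)
  }, numeric(1))
  if (anyNA(ses) || any(ses == 0)) {
    warning("missing or zero SEs: falling back to sample-size weights")
    w <- ns / sum(ns)
    est <- sum(w * vals)
    se <- if (anyNA(ses)) NA_real_ else sqrt(sum((w * ses)^2))
  } else {
    w <- 1 / ses^2
    est <- sum(w * vals) / sum(w)
    se <- sqrt(1 / sum(w))
  }
  structure(
    list(T_bound = est, se = se,
         ci95 = if (is.na(se)) c(NA_real_, NA_real_) else
           est + c(-1, 1) * 1.96 * se,
         n = sum(ns), inputs = estimates, pooled = TRUE),
    class = "bound_time_estimate"
  )
}
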