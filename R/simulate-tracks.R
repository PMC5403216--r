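#' Construct a track-duration sample
#'
#' A set of observed track durations together with the left-truncation point
#' implied by the minimum-localization acceptance threshold and the
#' acquisition settings under which they were recorded.
#'
#' @param durations Track durations in seconds; every duration must be at
#'   least `truncation_point`.
#' @param truncation_point Truncation point L in seconds
#'   (`min_localizations * interval_time`).
#' @param settings An [acquisition_settings()] object.
#' @param label Free-text label for reports.
#' @param truth Optional list of ground-truth parameters (populated by the
#'   generators).
#' @return An object of class `track_duration_sample`.
#' @export
track_duration_sample <- function(durations, truncation_point, settings,
                                  label = "", truth = NULL) {
  if (truncation_point < 0) stop_invalid("`truncation_point` must be >= 0")
  if (any(durations < truncation_point)) {
    stop_invalid("all durations must be >= the truncation point")
  }
  structure(
    list(durations = as.numeric(durations),
         truncation_point = truncation_point,
         settings = settings, label = label, truth = truth),
    class = "track_duration_sample"
  )
}

#' @export
print.track_duration_sample <- function(x, ...) {
  cat(sprintf("Track-duration sample%s: n = %d, L = %g s, mean = %.3g s\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              length(x$durations), x$truncation_point, mean(x$durations)))
  invisible(x)
}

# Number of frames survived by each molecule: visible in frame k iff still
# bound after k intervals and the accumulated exposure k * t_exp has not yet
# exhausted the bleaching budget. This makes the per-frame ending hazard
# interval/T_bound + exposure/T_constant, i.e. effective rates add
# (1/T_track = 1/T_bound + 1/T_bleach with T_bleach scaled by the duty
# cycle interval/exposure).
.simulate_frame_counts <- function(params, settings) {
  n <- params$n_molecules
  t_bind <- if (is.infinite(params$true_bound_time)) rep(Inf, n) else
    stats::rexp(n, rate = 1 / params$true_bound_time)
  e_bleach <- stats::rexp(n, rate = 1 / params$constant_exposure_bleach_time)
  n_bind <- floor(t_bind / settings$interval_time)
  n_bleach <- floor(e_bleach / settings$exposure_time)
  pmin(n_bind, n_bleach, settings$n_frames)
}

# Premature track termination through photoblinking: a dark gap that spans
# more than `memory` frames splits the track; only the first fragment is
# recorded (it is what the tracking software would report).
.apply_blink_termination <- function(frames, params, settings, memory) {
  if (params$blink_probability == 0) return(frames)
  n <- length(frames)
  blinks <- stats::runif(n) < params$blink_probability
  n_events <- ifelse(blinks,
                     stats::rgeom(n, prob = 1 / params$mean_blink_events) + 1L,
                     0L)
  for (i in which(n_events > 0L & frames > 1L)) {
    gaps <- stats::rexp(n_events[i], rate = 1 / params$blink_time_constant)
    missed <- floor(gaps / settings$interval_time)
    if (any(missed > memory)) {
      # gap positions are uniform over the molecule's visible span
      cut_at <- sample.int(frames[i] - 1L, 1L)
      frames[i] <- cut_at
    }
  }
  frames
}

#' Generate synthetic sptPALM track durations
#'
#' Observed track durations are the minimum of an exponential binding time
#' (mean `true_bound_time`) and an exponential photobleaching time that
#' accrues only during exposure, quantized to whole frames. Blink gaps
#' exceeding the tracking memory terminate tracks prematurely. Tracks with
#' fewer localizations than the per-interval acceptance threshold are
#' dropped, and the implied truncation point
#' `L = min_localizations * interval_time` is recorded with the sample.
#'
#' @param params A [track_sim_params()] object.
#' @param settings An [acquisition_settings()] object.
#' @param min_localizations Optional override of the per-interval minimum
#'   localization threshold (see [min_localizations_for()]).
#' @param memory Tracking memory in frames assumed when blink gaps are
#'   bridged (default 1).
#' @param label Sample label.
#' @return A [track_duration_sample()] with ground truth in `$truth`.
#' @export
#' @examples
#' s <- gen_track_durations(
#'   track_sim_params(true_bound_time = 10, n_molecules = 500, seed = 7),
#'   acquisition_settings(0.5, 1, 600)
#' )
#' s
gen_track_durations <- function(params, settings, min_localizations = NULL,
                                memory = 1L, label = "") {
  stopifnot(inherits(params, "track_sim_params"),
            inherits(settings, "acquisition_settings"))
  min_loc <- min_localizations_for(settings$interval_time,
                                   min_localizations = min_localizations)
  with_seed(params$seed, {
    frames <- .simulate_frame_counts(params, settings)
    frames <- .apply_blink_termination(frames, params, settings, memory)
    kept <- frames >= min_loc
    durations <- frames[kept] * settings$interval_time
    t_bleach <- bleach_time_scaled(params$constant_exposure_bleach_time,
                                   settings)
    truth <- list(
      params = params,
      true_bound_time = params$true_bound_time,
      t_bleach = t_bleach,
      t_track = 1 / (1 / params$true_bound_time + 1 / t_bleach),
      n_generated = params$n_molecules,
      n_kept = sum(kept)
    )
    track_duration_sample(durations, min_loc * settings$interval_time,
                          settings, label = label, truth = truth)
  })
}

#' Generate a photobleaching control sample
#'
#' Identical to [gen_track_durations()] with an effectively infinite bound
#' time, emulating a stable binder (LacI on an operator array) whose focus
#' lifetime is dictated by photobleaching alone.
#'
#' @inheritParams gen_track_durations
#' @export
gen_bleach_control <- function(params, settings, min_localizations = NULL,
                               memory = 1L, label = "bleach control") {
  params$true_bound_time <- Inf
  gen_track_durations(params, settings, min_localizations = min_localizations,
                      memory = memory, label = label)
}

#' Duty-cycle scaling of the bleaching time
#'
#' Bleaching accrues only while the shutter is open, so the effective bleach
#' time under stroboscopic acquisition is
#' `T_bleach = (interval_time / exposure_time) * T_constant`.
#'
#' @param t_constant Constant-exposure bleaching time, seconds.
#' @param settings An [acquisition_settings()] object.
#' @return Effective bleach time in seconds.
#' @export
bleach_time_scaled <- function(t_constant, settings) {
  check_positive(t_constant, "t_constant")
  (settings$interval_time / settings$exposure_time) * t_constant
}
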