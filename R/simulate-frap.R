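#' Generate synthetic FRAP recovery traces
#'
#' Per-focus intensity traces following the reaction-limited recovery model:
#' pre-bleach points have expectation 1, post-bleach points have expectation
#' `c - a exp(-b t)`, both multiplied by a global exponential photobleaching
#' decay (normalised to 1 at the first sampled time) and perturbed by
#' Gaussian noise.
#'
#' @param params A [frap_sim_params()] object.
#' @return A data.frame with columns `time_s`, `intensity`, `cell_id`,
#'   `roi_type` (`"focus"`), with attributes `n_prebleach` and `truth`.
#' @export
#' @examples
#' tr <- gen_frap_traces(frap_sim_params(asymptote = 0.8, amplitude = 0.5,
#'                                       unbinding_rate = 0.25, noise_sd = 0,
#'                                       n_traces = 1))
#' head(tr)
gen_frap_traces <- function(params) {
  stopifnot(inherits(params, "frap_sim_params"))
  t <- params$sample_times
  pre <- seq_len(params$n_prebleach)
  mu <- numeric(length(t))
  mu[pre] <- 1
  post <- setdiff(seq_along(t), pre)
  mu[post] <- params$asymptote -
    params$amplitude * exp(-params$unbinding_rate * t[post])
  decay <- if (is.finite(params$global_bleach_time)) {
    exp(-(t - t[1]) / params$global_bleach_time)
  } else rep(1, length(t))
  with_seed(params$seed, {
    out <- do.call(rbind, lapply(seq_len(params$n_traces), function(i) {
      data.frame(
        time_s = t,
        intensity = mu * decay + stats::rnorm(length(t), 0, params$noise_sd),
        cell_id = sprintf("cell%03d", i),
        roi_type = "focus"
      )
    }))
    attr(out, "n_prebleach") <- params$n_prebleach
    attr(out, "truth") <- params
    out
  })
}

#' Generate supporting FRAP ROI traces
#'
#' Whole-cell ROIs (for the maximum-recovery bound) and unbleached control
#' foci (for the acquisition-photobleaching baseline) matching the timing
#' and decay of [gen_frap_traces()]. A whole-cell trace drops from 1 to
#' `residual_fraction` at the bleach and then follows the global decay; a
#' control focus follows the decay alone.
#'
#' @param params A [frap_sim_params()] object.
#' @param residual_fraction Fraction of cellular fluorescence surviving the
#'   localized bleach (sets the ground-truth maximum recovery).
#' @param n_cells Number of cell / control traces.
#' @return A data.frame of traces with `roi_type` in
#'   `{"cell", "control_focus"}`.
#' @export
gen_frap_support_traces <- function(params, residual_fraction = 0.8,
                                    n_cells = 20L) {
  stopifnot(inherits(params, "frap_sim_params"))
  check_fraction(residual_fraction, "residual_fraction")
  t <- params$sample_times
  pre <- seq_len(params$n_prebleach)
  decay <- if (is.finite(params$global_bleach_time)) {
    exp(-(t - t[1]) / params$global_bleach_time)
  } else rep(1, length(t))
  cell_mu <- decay * ifelse(seq_along(t) %in% pre, 1, residual_fraction)
  with_seed(params$seed + 1L, {
    out <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
      rbind(
        data.frame(time_s = t,
                   intensity = cell_mu +
                     stats::rnorm(length(t), 0, params$noise_sd),
                   cell_id = sprintf("cell%03d", i), roi_type = "cell"),
        data.frame(time_s = t,
                   intensity = decay +
                     stats::rnorm(length(t), 0, params$noise_sd),
                   cell_id = sprintf("ctrl%03d", i),
                   roi_type = "control_focus")
      )
    }))
    attr(out, "n_prebleach") <- params$n_prebleach
    out
  })
}
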