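# shared fixtures and independent oracles

eps_settings <- function(n_frames = 600L) {
  acquisition_settings(exposure_time = 0.5, interval_time = 1,
                       n_frames = n_frames)
}

continuous_settings <- function(n_frames = 2000L) {
  acquisition_settings(exposure_time = 0.5, interval_time = 0.5,
                       n_frames = n_frames)
}

# Brute-force frame-stepping simulator: one Bernoulli survival draw per
# frame for binding and for bleaching. Independent of the vectorized
# generator implementation.
brute_force_frame_counts <- function(n, t_bound, t_constant, settings,
                                     seed) {
  p_bind <- exp(-settings$interval_time / t_bound)
  p_bleach <- exp(-settings$exposure_time / t_constant)
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      k <- 0L
      while (k < settings$n_frames) {
        if (stats::runif(1) > p_bind || stats::runif(1) > p_bleach) break
        k <- k + 1L
      }
      k
    }, integer(1))
  })
}

# minimal hand-built localization table
loc_table <- function(frame, x, y, sigma_x = 100, sigma_y = 100,
                      intensity = 1000, background = 50) {
  n <- length(frame)
  tab <- data.frame(
    frame = as.integer(frame), x_nm = x, y_nm = y,
    sigma_x_nm = rep_len(sigma_x, n), sigma_y_nm = rep_len(sigma_y, n),
    intensity = rep_len(intensity, n), background = rep_len(background, n)
  )
  tab[order(tab$frame), , drop = FALSE]
}

# standard bleach calibration used across dwell tests (large control so the
# calibration itself contributes little error)
std_calibration <- function(seed = 42L, n = 2000L) {
  calibrate_bleach(gen_bleach_control(
    track_sim_params(Inf, n_molecules = n, seed = seed),
    continuous_settings(), min_localizations = 4))
}
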