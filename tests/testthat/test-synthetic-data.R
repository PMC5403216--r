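test_that("pure-bleaching and pure-binding limits give the expected means", {
  st <- eps_settings()

  # binding term vanishes: mean duration ~ scaled bleach time
  s_bleach <- gen_track_durations(
    track_sim_params(Inf, constant_exposure_bleach_time = 15,
                     blink_probability = 0, n_molecules = 1500, seed = 1),
    st, min_localizations = 1)
  t_bleach <- bleach_time_scaled(15, st)  # 30 s
  fit <- fit_truncated_exponential(s_bleach, grid_correction = TRUE)
  expect_lt(abs(fit$tau - t_bleach), 3 * fit$se)

  # bleaching term vanishes: mean - L ~ true bound time (continuous scale,
  # allowing the half-interval quantization offset)
  s_bind <- gen_track_durations(
    track_sim_params(10, constant_exposure_bleach_time = 1e9,
                     blink_probability = 0, n_molecules = 1500, seed = 2),
    st)
  fit2 <- fit_truncated_exponential(s_bind, grid_correction = TRUE)
  expect_lt(abs(fit2$tau - 10), 3 * fit2$se)
})

test_that("track-ending hazard matches a brute-force frame-stepping oracle", {
  st <- eps_settings()
  params <- track_sim_params(10, constant_exposure_bleach_time = 15,
                             blink_probability = 0, n_molecules = 10000,
                             seed = 11)
  s <- gen_track_durations(params, st, min_localizations = 1)
  frames <- s$durations / st$interval_time

  oracle <- brute_force_frame_counts(10000, 10, 15, st, seed = 12)
  oracle <- oracle[oracle >= 1]

  # per-frame survival probability q = exp(-h), h = 1/10 + 1/30 per second
  h_true <- 1 / 10 + 1 / 30
  q_gen <- mean(frames - 1) / mean(frames)       # MLE of geometric survival
  q_orc <- mean(oracle - 1) / mean(oracle)
  expect_equal(-log(q_gen) / st$interval_time, h_true, tolerance = 0.03)
  expect_equal(mean(frames), mean(oracle), tolerance = 0.03)
})

test_that("durations are frame-quantized, truncated at L, and seed-stable", {
  st <- acquisition_settings(0.5, 2, 500)
  params <- track_sim_params(20, n_molecules = 400, seed = 9)
  s1 <- gen_track_durations(params, st)
  s2 <- gen_track_durations(params, st)
  expect_identical(s1$durations, s2$durations)
  expect_true(all(s1$durations %% st$interval_time == 0))
  expect_true(all(s1$durations >= s1$truncation_point))
  expect_identical(s1$truncation_point,
                   min_localizations_for(2) * st$interval_time)

  expect_error(track_sim_params(-1), "positive")
  expect_error(track_sim_params(10, constant_exposure_bleach_time = 0),
               "positive")
})

test_that("bleach control reproduces the duty-cycle scaling of bleach time", {
  # interval = exposure: mean track constant ~ T_constant
  ctrl1 <- gen_bleach_control(
    track_sim_params(Inf, constant_exposure_bleach_time = 20,
                     blink_probability = 0, n_molecules = 1500, seed = 5),
    continuous_settings(), min_localizations = 2)
  f1 <- fit_truncated_exponential(ctrl1, grid_correction = TRUE)
  expect_lt(abs(f1$tau - 20), 3 * f1$se)

  # 0.5 s exposure spaced 5 s: tenfold longer apparent bleach time
  st5 <- acquisition_settings(0.5, 5, 600)
  ctrl2 <- gen_bleach_control(
    track_sim_params(Inf, constant_exposure_bleach_time = 20,
                     blink_probability = 0, n_molecules = 1500, seed = 6),
    st5)
  f2 <- fit_truncated_exponential(ctrl2, grid_correction = TRUE)
  expect_lt(abs(f2$tau - 200), 3 * f2$se)

  # closed-form MLE recovers the scaled bleach time at large n
  ctrl3 <- gen_bleach_control(
    track_sim_params(Inf, constant_exposure_bleach_time = 15,
                     blink_probability = 0, n_molecules = 10000, seed = 7),
    eps_settings())
  f3 <- fit_truncated_exponential(ctrl3, grid_correction = TRUE)
  expect_lt(abs(f3$tau - 30), 3 * f3$se)
})

test_that("localization tables have the configured PSF structure", {
  st <- acquisition_settings(0.5, 1, 150)
  mix <- mixture_spec(n_diffusing = 120)
  tab <- gen_localization_table(
    track_sim_params(10, n_molecules = 120, seed = 3), st, mix)

  expect_true(all(diff(tab$frame) >= 0))
  expect_named(tab, c("frame", "x_nm", "y_nm", "sigma_x_nm", "sigma_y_nm",
                      "intensity", "background"))

  # bimodal PSF histogram with modes near the configured 100 / 200 nm
  fit <- fit_psf_mixture(tab$sigma_x_nm)
  expect_equal(fit$mean[1], 100, tolerance = 0.1)
  expect_equal(fit$mean[2], 200, tolerance = 0.1)

  expect_error(gen_localization_table(
    track_sim_params(10, n_molecules = 10, seed = 1), st, mixture = list()),
    "mixture_spec")
})

test_that("clean tables give exactly one track per ground-truth molecule", {
  st <- acquisition_settings(0.5, 1, 100)
  mix <- mixture_spec(n_diffusing = 0, localization_noise_sd = 0)

  # no blinking, no noise, no diffusers
  tab <- gen_localization_table(
    track_sim_params(10, blink_probability = 0, n_molecules = 40, seed = 8),
    st, mix)
  tracks <- link_localizations(tab)
  expect_identical(length(unique(tracks$track_id)),
                   length(unique(attr(tab, "truth")$molecule)))

  # blinking at 50% with gaps clipped to the memory window: the memory
  # parameter bridges every gap, so the track count still matches
  tab2 <- gen_localization_table(
    track_sim_params(10, blink_probability = 0.5, n_molecules = 40,
                     seed = 13),
    st, mix, clip_blink_gaps_to = 1L)
  tracks2 <- link_localizations(tab2, memory = 1L)
  expect_identical(length(unique(tracks2$track_id)),
                   length(unique(attr(tab2, "truth")$molecule)))
})

test_that("localization table round-trips through CSV with truth sidecar", {
  st <- acquisition_settings(0.5, 1, 50)
  tab <- gen_localization_table(
    track_sim_params(10, n_molecules = 15, seed = 4), st,
    mixture_spec(n_diffusing = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_localization_table(tab, path)
  back <- read_localization_table(path)
  expect_equal(as.data.frame(back)[names(back) != "frame"],
               as.data.frame(tab)[names(tab) != "frame"], tolerance = 1e-12)
  expect_equal(attr(back, "truth")$molecule, attr(tab, "truth")$molecule)
})

test_that("FRAP traces follow the recovery model", {
  # noiseless, no global bleaching: exact model values
  p <- frap_sim_params(asymptote = 0.8, amplitude = 0.5,
                       unbinding_rate = 0.25, global_bleach_time = Inf,
                       noise_sd = 0, n_traces = 1, seed = 1)
  tr <- gen_frap_traces(p)
  post <- tr$time_s >= 0
  expect_equal(tr$intensity[post],
               0.8 - 0.5 * exp(-0.25 * tr$time_s[post]), tolerance = 1e-12)
  expect_equal(tr$intensity[tr$time_s == 0], 0.8 - 0.5)  # c - a at t = 0
  expect_equal(tr$intensity[!post], c(1, 1))

  # noisy ensemble averages to the analytic mean within Monte-Carlo error
  p2 <- frap_sim_params(0.8, 0.5, 0.25, global_bleach_time = Inf,
                        noise_sd = 0.02, n_traces = 200, seed = 2)
  avg <- average_and_collate(gen_frap_traces(p2))
  mu <- ifelse(avg$time_s < 0, 1, 0.8 - 0.5 * exp(-0.25 * avg$time_s))
  mc_se <- 0.02 / sqrt(200)
  expect_true(all(abs(avg$intensity - mu) < 4 * mc_se))

  expect_error(frap_sim_params(0.5, 0.8, 0.2), "asymptote")
  expect_error(frap_sim_params(0.8, 0.5, 0.2, sample_times = c(-1, 0, 0, 1)),
               "increasing")
})
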