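test_that("truncated-exponential MLE equals mean minus L in closed form", {
  st <- acquisition_settings(0.5, 1)
  s <- track_duration_sample(c(3, 4, 8), 2, st)
  expect_equal(fit_truncated_exponential(s)$tau, 3)

  s1 <- track_duration_sample(7, 4, st)
  expect_equal(fit_truncated_exponential(s1)$tau, 3)

  # property: mean - L to machine precision on random samples
  withr::with_seed(10, {
    for (i in 1:20) {
      L <- runif(1, 0, 5)
      x <- L + rexp(50, 1 / runif(1, 1, 30))
      sm <- track_duration_sample(x, L, st)
      expect_equal(fit_truncated_exponential(sm)$tau, mean(x) - L,
                   tolerance = 1e-14)
    }
  })

  expect_error(track_duration_sample(c(1, 5), 2, st), "truncation")
  expect_error(
    fit_truncated_exponential(track_duration_sample(c(4, 4), 4, st)),
    "degenerate")
})

test_that("the MLE recovers a known simulated time constant", {
  st <- acquisition_settings(0.5, 1)
  x <- withr::with_seed(11, 4 + rexp(10000, 1 / 10))
  f <- fit_truncated_exponential(track_duration_sample(x, 4, st))
  expect_lt(abs(f$tau - 10), 3 * 10 / sqrt(10000))
  expect_true(f$ci95[1] <= f$tau && f$tau <= f$ci95[2])
})

test_that("ignoring the truncation point biases the estimate upward", {
  st <- acquisition_settings(0.5, 1)
  x <- withr::with_seed(12, 4 + rexp(5000, 1 / 10))
  tau_with_L <- fit_truncated_exponential(
    track_duration_sample(x, 4, st))$tau
  tau_no_L <- mean(x)  # plain exponential MLE, truncation ignored
  expect_gt(tau_no_L, tau_with_L + 3.5)
})

test_that("grid correction removes the frame-quantization bias", {
  st <- eps_settings()
  s <- gen_track_durations(
    track_sim_params(10, constant_exposure_bleach_time = 1e9,
                     blink_probability = 0, n_molecules = 20000, seed = 14),
    st)
  f_cont <- fit_truncated_exponential(s)
  f_grid <- fit_truncated_exponential(s, grid_correction = TRUE)
  # the continuous form understates tau by about half an interval
  expect_lt(f_cont$tau, 10 - 0.25)
  expect_lt(abs(f_grid$tau - 10), 3 * f_grid$se)
})

test_that("bleach correction satisfies the rate-sum identity", {
  expect_equal(correct_bound_time(5, 10), 10)
  expect_equal(correct_bound_time(10, 30), 15)
  expect_equal(correct_bound_time(2, 1000), 2 * 1000 / 998)  # ~2.004

  # property: inverting 1/T_track = 1/T_bound + 1/T_bleach round-trips
  withr::with_seed(15, {
    for (i in 1:25) {
      t_bound <- runif(1, 0.5, 500)
      t_bleach <- runif(1, 0.5, 500)
      t_track <- 1 / (1 / t_bound + 1 / t_bleach)
      expect_equal(correct_bound_time(t_track, t_bleach), t_bound,
                   tolerance = 1e-12)
    }
  })

  expect_error(correct_bound_time(10, 10), "not identifiable")
  expect_error(correct_bound_time(12, 10), "not identifiable")
})

test_that("bleach calibration scales by the duty cycle", {
  st_c <- acquisition_settings(0.5, 0.5)
  # control fitted at constant exposure: tau is T_constant directly
  ctrl <- track_duration_sample(withr::with_seed(16, 1 + rexp(500, 1 / 20)),
                                1, st_c)
  cal <- calibrate_bleach(ctrl, grid_correction = FALSE)
  expect_equal(cal$T_constant, cal$fit$tau)
  st5 <- acquisition_settings(0.5, 5)
  expect_equal(bleach_time_at(cal, st5), 10 * cal$T_constant)
  expect_equal(bleach_time_at(cal, st_c), cal$T_constant)
  # a plain number is treated as a constant-exposure bleach time
  expect_equal(bleach_time_at(20, st5), 200)

  # synthetic stable binder: recovered within 3 SE
  cal2 <- std_calibration(seed = 17)
  expect_lt(abs(cal2$T_constant - 15), 4 * cal2$fit$se)
})

test_that("weighted averaging is inverse-variance with sane fallbacks", {
  mk <- function(v, se, n = 100) {
    structure(list(T_bound = v, se = se, n = n),
              class = "bound_time_estimate")
  }
  expect_equal(weighted_average(list(mk(10, 1), mk(20, 1)))$T_bound, 15)
  expect_equal(weighted_average(list(mk(10, 1), mk(20, 2)))$T_bound, 12)
  w <- weighted_average(list(mk(10, 1), mk(20, 2)))
  expect_equal(w$se, sqrt(1 / (1 + 0.25)))
  expect_identical(weighted_average(list(mk(7, 0.5)))$T_bound, 7)
  expect_warning(weighted_average(list(mk(10, NA), mk(20, 1))), "weights")
})

test_that("bootstrap estimate is deterministic with sensible edge cases", {
  st <- eps_settings()
  s <- track_duration_sample(withr::with_seed(18, 4 + rexp(150, 1 / 7)), 4,
                             st)
  e1 <- bootstrap_estimate(s, 15, n_boot = 500, seed = 99)
  e2 <- bootstrap_estimate(s, 15, n_boot = 500, seed = 99)
  expect_identical(e1$ci95, e2$ci95)
  expect_identical(e1$T_bound, e2$T_bound)
  expect_true(e1$ci95[1] < e1$T_bound && e1$T_bound < e1$ci95[2])

  # identical durations: zero-width interval
  sd0 <- track_duration_sample(rep(8, 30), 4, st)
  e0 <- bootstrap_estimate(sd0, 15, n_boot = 500, seed = 1,
                           grid_correction = FALSE)
  expect_equal(diff(e0$ci95), 0)
  expect_equal(e0$se, 0)

  expect_error(bootstrap_estimate(s, 15, n_boot = 50), "at least 100")
})

test_that("the BCa interval matches boot::boot.ci on a one-sample statistic", {
  skip_if_not_installed("boot")
  st <- eps_settings()
  x <- withr::with_seed(19, 4 + rexp(120, 1 / 9))
  s <- track_duration_sample(x, 4, st)
  # fixed bleach time so the statistic depends on one sample only
  est <- bootstrap_estimate(s, 15, n_boot = 4000, seed = 7,
                            grid_correction = FALSE)

  stat <- function(d, idx) {
    tau <- mean(d[idx]) - 4
    tau * 30 / (30 - tau)
  }
  ref <- withr::with_seed(7, boot::boot(x, stat, R = 4000))
  ci_ref <- boot::boot.ci(ref, type = "bca")$bca[4:5]
  # independent resampling streams: agree to Monte-Carlo accuracy
  expect_equal(est$ci95[1], ci_ref[1], tolerance = 0.05)
  expect_equal(est$ci95[2], ci_ref[2], tolerance = 0.05)
})
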