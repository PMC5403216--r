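mk_trace <- function(times, intensity, cell = "c1", roi = "focus") {
  data.frame(time_s = times, intensity = intensity, cell_id = cell,
             roi_type = roi)
}

test_that("trace filters enforce the bleach-quality rules", {
  t <- c(-10, -5, 0, 5, 10)
  # 0 s at 50% of pre-bleach mean: rejected
  bad40 <- mk_trace(t, c(1, 1, 0.5, 0.6, 0.7), "a")
  # 0 s at 30%, pre-bleach above it: kept
  good <- mk_trace(t, c(1, 1, 0.3, 0.5, 0.7), "b")
  # a pre-bleach point below the 0 s value: rejected
  badpre <- mk_trace(t, c(1, 0.2, 0.3, 0.5, 0.7), "c")
  out <- filter_traces(rbind(bad40, good, badpre))
  expect_identical(unique(out$cell_id), "b")
  expect_identical(attr(out, "n_rejected"), 2L)
})

test_that("normalization fixes the pre-bleach mean at exactly 1", {
  tr <- mk_trace(c(-10, -5, 0, 5), c(100, 104, 30, 60))
  nn <- normalize_trace(tr)
  expect_equal(mean(nn$intensity[nn$time_s < 0]), 1, tolerance = 1e-15)
  expect_equal(nn$intensity, c(100, 104, 30, 60) / 102)

  flat <- mk_trace(c(-10, -5, 0, 5), rep(80, 4))
  expect_equal(normalize_trace(flat)$intensity, rep(1, 4))

  expect_error(normalize_trace(mk_trace(c(-5, 0, 5), c(0, 1, 1))), "zero")
})

test_that("maximum recovery is the surviving cell-intensity fraction", {
  t <- c(-10, -5, 0, 5)
  cells <- rbind(mk_trace(t, c(1, 1, 0.8, 0.8), "c1", "cell"),
                 mk_trace(t, c(2, 2, 1.4, 1.4), "c2", "cell"))
  expect_equal(estimate_max_recovery(cells), mean(c(0.8, 0.7)))
  # fully bleached cell
  dead <- mk_trace(t, c(1, 1, 0, 0), "c3", "cell")
  expect_equal(estimate_max_recovery(dead), 0)

  # generator accounting: configured residual fraction, noiseless
  p <- frap_sim_params(0.8, 0.5, 0.25, noise_sd = 0, n_traces = 2, seed = 1)
  sup <- gen_frap_support_traces(p, residual_fraction = 0.75, n_cells = 4)
  expect_equal(estimate_max_recovery(sup), 0.75, tolerance = 1e-12)
})

test_that("photobleach correction divides by the normalized decay", {
  t <- seq(-10, 60, by = 5)
  decay <- exp(-(t + 10) / 100)
  ctrl <- mk_trace(t, decay, "ctrl1", "control_focus")
  baseline <- fit_bleach_baseline(ctrl)
  expect_equal(baseline$decay_time, 100, tolerance = 1e-6)

  # a generator-applied decay of the same constant cancels exactly
  mu <- ifelse(t < 0, 1, 0.8 - 0.5 * exp(-0.25 * t))
  tr <- mk_trace(t, mu * decay)
  corrected <- correct_photobleach(tr, baseline)
  expect_equal(corrected$intensity, mu, tolerance = 1e-9)

  # a flat baseline is the identity
  flat <- fit_bleach_baseline(mk_trace(t, rep(1, length(t)), "x",
                                       "control_focus"))
  tr2 <- mk_trace(t, mu)
  expect_equal(correct_photobleach(tr2, flat)$intensity, mu,
               tolerance = 1e-6)

  # correction never decreases intensities under a decaying baseline
  expect_true(all(corrected$intensity >= tr$intensity - 1e-12))

  expect_error(correct_photobleach(mk_trace(100, 1), baseline), "cover")
})

test_that("collation merges distinct time grids on their union", {
  a <- mk_trace(c(-5, 0, 2, 4), c(1, 0.3, 0.4, 0.5), "a")
  b <- mk_trace(c(-5, 0, 5, 10), c(1, 0.3, 0.6, 0.7), "b")
  m <- average_and_collate(a, b)
  expect_identical(m$time_s, c(-5, 0, 2, 4, 5, 10))
  expect_equal(m$intensity[m$time_s == 0], 0.3)
  expect_identical(m$n_traces[m$time_s == 0], 2L)
  expect_identical(m$n_traces[m$time_s == 5], 1L)

  # identical traces: mean equals each
  m2 <- average_and_collate(a, a)
  expect_equal(m2$intensity, a$intensity)
})

test_that("recovery fitting is exact on noiseless data and respects the cap", {
  t <- seq(0, 60, by = 2)
  y <- 0.8 - 0.5 * exp(-0.25 * t)
  fit <- fit_recovery(data.frame(time_s = t, intensity = y),
                      max_recovery = 1, n_boot = 0)
  expect_equal(fit$c, 0.8, tolerance = 1e-6)
  expect_equal(fit$a, 0.5, tolerance = 1e-6)
  expect_equal(fit$b, 0.25, tolerance = 1e-6)
  expect_equal(fit$bound_time, 4, tolerance = 1e-5)
  expect_equal(y[1], fit$c - fit$a, tolerance = 1e-6)  # value at t=0 is c-a

  # asymptote bounded by 1.1 * max recovery
  fit2 <- fit_recovery(data.frame(time_s = t, intensity = y),
                       max_recovery = 0.6, n_boot = 0)
  expect_lte(fit2$c, 1.1 * 0.6 + 1e-9)

  expect_error(fit_recovery(data.frame(time_s = 0:3, intensity = 1:4)),
               "at least 5")
})

test_that("bound times are invariant to rescaling raw intensities", {
  p <- frap_sim_params(0.8, 0.5, 0.25, noise_sd = 0.02, n_traces = 20,
                       seed = 3)
  tr <- gen_frap_traces(p)
  run <- function(scale) {
    tr$intensity <- tr$intensity * scale
    mt <- average_and_collate(normalize_trace(filter_traces(tr)))
    fit_recovery(mt, n_boot = 0)$bound_time
  }
  expect_equal(run(1), run(137.5), tolerance = 1e-6)
})

test_that("the alpha-subunit regime is recovered from noisy ensembles", {
  p <- frap_sim_params(0.8, 0.55, 0.25, global_bleach_time = 200,
                       noise_sd = 0.05, n_traces = 48, seed = 4)
  traces <- rbind(gen_frap_traces(p),
                  gen_frap_support_traces(p, residual_fraction = 0.85,
                                          n_cells = 20))
  rep <- run_frap_pipeline(traces, run_config(acquisition_settings(0.3),
                                              n_boot = 300, seed = 5))
  fit <- rep$fit
  expect_identical(fit$status, "ok")
  # truth bound time 1/0.25 = 4 s, within 2 bootstrap SE
  se_bt <- fit$se[["b"]] / fit$b^2
  expect_lt(abs(fit$bound_time - 4), 2 * se_bt)
  expect_gt(fit$ks_p, 0.01)
})

test_that("non-recovering traces are flagged as not estimable", {
  p <- frap_sim_params(0.32, 0.3, 0.004, noise_sd = 0.03, n_traces = 30,
                       seed = 6)
  rep <- run_frap_pipeline(gen_frap_traces(p),
                           run_config(acquisition_settings(0.3),
                                      n_boot = 200, seed = 7))
  expect_identical(rep$fit$status, "bound-time not estimable")
})
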