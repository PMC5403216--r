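#' Filter FRAP traces for clean bleaching events
#'
#' Keeps only per-focus traces where the bleach clearly worked: a trace is
#' removed when any pre-bleach intensity lies below the value immediately
#' after bleaching (the 0 s point), or when the 0 s intensity is not below
#' 40% of the mean pre-bleach intensity.
#'
#' @param traces Data.frame with columns `time_s`, `intensity`, `cell_id`,
#'   `roi_type`; pre-bleach points at negative times, the bleach at t = 0.
#' @return The filtered traces (focus rows only), with attribute
#'   `n_rejected`.
#' @export
filter_traces <- function(traces) {
  foc <- traces[traces$roi_type == "focus", , drop = FALSE]
  keep <- vapply(split(seq_len(nrow(foc)), foc$cell_id), function(idx) {
    tr <- foc[idx, , drop = FALSE]
    pre <- tr$intensity[tr$time_s < 0]
    at0 <- tr$intensity[which.min(abs(tr$time_s))]
    if (length(pre) < 1L || length(at0) != 1L) return(FALSE)
    all(pre >= at0) && at0 < 0.4 * mean(pre)
  }, logical(1))
  kept_cells <- names(keep)[keep]
  out <- foc[foc$cell_id %in% kept_cells, , drop = FALSE]
  attr(out, "n_prebleach") <- attr(traces, "n_prebleach")
  attr(out, "n_rejected") <- sum(!keep)
  out
}

#' Normalize traces by their pre-bleach mean
#'
#' After normalization each cell's pre-bleach mean is exactly 1, so
#' recovery is expressed as a fraction of the original focus intensity.
#' Vectorizes over cells.
#'
#' @param traces Data.frame as in [filter_traces()].
#' @return Normalized traces.
#' @export
normalize_trace <- function(traces) {
  out <- traces
  for (cell in unique(traces$cell_id)) {
    idx <- traces$cell_id == cell
    pre <- traces$intensity[idx & traces$time_s < 0]
    m <- mean(pre)
    if (!is.finite(m) || m == 0) {
      stop_invalid("zero or missing pre-bleach mean for cell ", cell)
    }
    out$intensity[idx] <- traces$intensity[idx] / m
  }
  attr(out, "n_prebleach") <- attr(traces, "n_prebleach")
  out
}

#' Maximum possible fluorescence recovery
#'
#' Localized bleaching inevitably removes part of the cell's fluorescent
#' pool, capping how far a focus can recover. The bound is estimated from
#' whole-cell ROI traces as the mean over cells of (cell intensity at 0 s /
#' pre-bleach mean).
#'
#' @param cell_traces Data.frame of whole-cell traces
#'   (`roi_type == "cell"`).
#' @return Normalized maximum recovery (scalar).
#' @export
estimate_max_recovery <- function(cell_traces) {
  cc <- cell_traces[cell_traces$roi_type == "cell", , drop = FALSE]
  if (nrow(cc) == 0L) stop_invalid("no whole-cell ROI traces supplied")
  vals <- vapply(split(seq_len(nrow(cc)), cc$cell_id), function(idx) {
    tr <- cc[idx, , drop = FALSE]
    pre <- tr$intensity[tr$time_s < 0]
    at0 <- tr$intensity[which.min(abs(tr$time_s))]
    at0 / mean(pre)
  }, numeric(1))
  mean(vals)
}

#' Fit the acquisition-photobleaching baseline
#'
#' Unbleached control foci fade during imaging; their averaged intensity
#' trace is fitted to a single exponential decay `A exp(-t/T)` (free
#' amplitude) and used, normalized to 1 at the first time point, to correct
#' FRAP traces.
#'
#' @param control_traces Data.frame of unbleached-focus traces
#'   (`roi_type == "control_focus"`).
#' @return An object of class `bleach_baseline`: `amplitude`, `decay_time`,
#'   `t0`.
#' @export
fit_bleach_baseline <- function(control_traces) {
  ct <- control_traces[control_traces$roi_type == "control_focus", ,
                       drop = FALSE]
  if (nrow(ct) == 0L) stop_invalid("no control-focus traces supplied")
  mean_curve <- stats::aggregate(intensity ~ time_s, data = ct, FUN = mean)
  t <- mean_curve$time_s; y <- mean_curve$intensity
  # log-linear start, then nonlinear refinement
  pos <- y > 0
  st <- stats::lm(log(y[pos]) ~ t[pos])
  A0 <- exp(stats::coef(st)[1L])
  T0 <- -1 / min(stats::coef(st)[2L], -1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-t / Td),
      start = list(A = A0, Td = T0),
      lower = c(A = 1e-9, Td = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # a flat control (no measurable fading) leaves the decay time
    # unidentified; treat the baseline as constant
    if (stats::sd(y) < 1e-6 * mean(abs(y))) {
      return(structure(list(amplitude = mean(y), decay_time = Inf,
                            t0 = min(t), times = range(t)),
                       class = "bleach_baseline"))
    }
    stop_invalid("bleach-baseline fit failed")
  }
  cf <- stats::coef(fit)
  structure(
    list(amplitude = unname(cf["A"]), decay_time = unname(cf["Td"]),
         t0 = min(t), times = range(t)),
    class = "bleach_baseline"
  )
}

#' Normalized baseline value at given times
#'
#' @param baseline A [fit_bleach_baseline()] result.
#' @param t Times in seconds.
#' @return Decay values, equal to 1 at the baseline's first time point.
#' @export
baseline_at <- function(baseline, t) {
  exp(-(t - baseline$t0) / baseline$decay_time)
}

#' Correct FRAP traces for acquisition photobleaching
#'
#' Divides each intensity point by the fitted, normalized bleaching decay at
#' the same time, undoing the slow fade of the whole field.
#'
#' @param traces Normalized traces.
#' @param baseline A [fit_bleach_baseline()] result; its fitted span must
#'   cover the traces' times.
#' @return Corrected traces.
#' @export
correct_photobleach <- function(traces, baseline) {
  if (min(traces$time_s) < baseline$times[1L] - 1e-9 ||
      max(traces$time_s) > baseline$times[2L] + 1e-9) {
    stop_invalid("baseline fit does not cover the traces' time span")
  }
  denom <- baseline_at(baseline, traces$time_s)
  if (any(denom <= 0)) stop_invalid("non-positive baseline value")
  out <- traces
  out$intensity <- traces$intensity / denom
  attr(out, "n_prebleach") <- attr(traces, "n_prebleach")
  out
}

#' Collate traces into a mean recovery curve
#'
#' Experiments run with different sampling intervals are merged on the
#' union of their time grids; the mean intensity over available traces is
#' taken at each time point.
#'
#' @param ... One or more trace data.frames (normalized, bleach-corrected).
#' @return Data.frame with `time_s`, `intensity` (mean) and `n_traces`.
#' @export
average_and_collate <- function(...) {
  all <- do.call(rbind, lapply(list(...), function(tr) {
    tr[, c("time_s", "intensity"), drop = FALSE]
  }))
  agg <- stats::aggregate(intensity ~ time_s, data = all, FUN = mean)
  cnt <- stats::aggregate(intensity ~ time_s, data = all, FUN = length)
  out <- data.frame(time_s = agg$time_s, intensity = agg$intensity,
                    n_traces = cnt$intensity)
  out[order(out$time_s), , drop = FALSE]
}

#' Fit the reaction-limited FRAP recovery model
#'
#' Nonlinear least squares of `y = c - a exp(-b t)` to the post-bleach
#' points (t >= 0) of a mean recovery curve. The asymptote `c` is bounded
#' above by `1.1 * max_recovery` (the photobleaching-corrected recovery
#' ceiling plus 10% measurement allowance). The bound time is `1/b`.
#' Goodness of fit is assessed by a Kolmogorov-Smirnov test of residual
#' normality. When the per-cell trace set is supplied, standard errors and
#' 95% CIs come from bootstrap resampling of whole traces (respecting
#' per-cell correlation); otherwise asymptotic errors are reported. A fit
#' whose rate CI includes zero (no significant recovery) is flagged
#' `"bound-time not estimable"`, the behaviour expected of a stably bound
#' helicase.
#'
#' @param mean_trace Data.frame with `time_s` and `intensity` (from
#'   [average_and_collate()]).
#' @param max_recovery Maximum possible recovery from
#'   [estimate_max_recovery()] (default 1).
#' @param traces Optional per-cell trace set for bootstrap resampling.
#' @param n_boot Bootstrap samples (default 10000; 0 disables).
#' @param seed Seed for the bootstrap.
#' @return An object of class `frap_fit`: `c`, `a`, `b`, `bound_time`,
#'   `se` (named), `ci95` (list), `max_recovery`, `ks_p`, `status`, `n`.
#' @export
fit_recovery <- function(mean_trace, max_recovery = 1, traces = NULL,
                         n_boot = 10000L, seed = 1L) {
  post <- mean_trace[mean_trace$time_s >= 0, , drop = FALSE]
  if (nrow(post) < 5L) stop_invalid("need at least 5 post-bleach points")
  t <- post$time_s; y <- post$intensity
  c_upper <- 1.1 * max_recovery

  fit1 <- function(t, y) {
    c0 <- min(max(utils::tail(y, 3L)), c_upper * 0.999)
    a0 <- max(c0 - y[1L], 1e-3)
    best <- NULL
    for (b0 in c(0.01, 0.05, 0.2, 0.5, 1)) {
      o <- tryCatch(
        minpack.lm::nlsLM(
          y ~ cc - aa * exp(-bb * t),
          start = list(cc = c0, aa = a0, bb = b0),
          lower = c(cc = 1e-6, aa = 1e-9, bb = 1e-9),
          upper = c(cc = c_upper, aa = 2 * c_upper, bb = 100),
          control = minpack.lm::nls.lm.control(maxiter = 300)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) ||
                          sum(stats::resid(o)^2) < sum(stats::resid(best)^2)))
        best <- o
    }
    if (is.null(best)) {
      stop_invalid("recovery fit failed from all starting rates ",
                   "(tried b0 in {0.01, 0.05, 0.2, 0.5, 1})")
    }
    best
  }

  fit <- fit1(t, y)
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  ks_p <- if (stats::sd(res) > 0) {
    suppressWarnings(stats::ks.test(res, "pnorm", 0, stats::sd(res)))$p.value
  } else NA_real_

  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3L))
  names(se) <- c("c", "a", "b")
  ci <- list(c = cf["cc"] + c(-1, 1) * 1.96 * se["c"],
             a = cf["aa"] + c(-1, 1) * 1.96 * se["a"],
             b = cf["bb"] + c(-1, 1) * 1.96 * se["b"])

  if (!is.null(traces) && n_boot > 0L) {
    cells <- unique(traces$cell_id)
    boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        pick <- sample(cells, length(cells), replace = TRUE)
        bt <- do.call(rbind, lapply(pick, function(cl) {
          traces[traces$cell_id == cl, , drop = FALSE]
        }))
        mt <- average_and_collate(bt)
        o <- tryCatch(fit1(mt$time_s[mt$time_s >= 0],
                           mt$intensity[mt$time_s >= 0]),
                      error = function(e) NULL)
        if (is.null(o)) rep(NA_real_, 3L) else stats::coef(o)
      }, numeric(3L))
    })
    ok <- colSums(is.na(boot)) == 0L
    if (sum(ok) >= 100L) {
      bse <- unname(apply(boot[, ok, drop = FALSE], 1L, stats::sd))
      se <- c(c = bse[1L], a = bse[2L], b = bse[3L])
      qs <- apply(boot[, ok, drop = FALSE], 1L, stats::quantile,
                  probs = c(0.025, 0.975))
      ci <- list(c = qs[, 1L], a = qs[, 2L], b = qs[, 3L])
    }
  }

  b_ok <- is.finite(se["b"]) && (cf["bb"] - 1.96 * se["b"]) > 0
  status <- if (!b_ok || cf["aa"] < 1e-6) "bound-time not estimable" else "ok"

  structure(
    list(c = unname(cf["cc"]), a = unname(cf["aa"]), b = unname(cf["bb"]),
         bound_time = unname(1 / cf["bb"]),
         se = se, ci95 = lapply(ci, unname),
         max_recovery = max_recovery, ks_p = unname(ks_p),
         status = status, n = nrow(post)),
    class = "frap_fit"
  )
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "FRAP fit: c = %.3f, a = %.3f, b = %.3g /s -> bound time %.3g s [%s]\n",
    x$c, x$a, x$b, x$bound_time, x$status))
  invisible(x)
}

#' Write / read FRAP traces as CSV
#'
#' Columns: `time_s`, `intensity`, `cell_id`,
#' `roi_type` in focus / cell / control_focus.
#'
#' @param traces Trace data.frame.
#' @param path CSV path.
#' @param n_prebleach Pre-bleach point count recorded on read.
#' @export
write_frap_traces <- function(traces, path) {
  utils::write.csv(as.data.frame(traces), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frap_traces
#' @export
read_frap_traces <- function(path, n_prebleach = 2L) {
  tr <- utils::read.csv(path)
  needed <- c("time_s", "intensity", "cell_id", "roi_type")
  if (!all(needed %in% names(tr))) {
    stop_invalid("FRAP CSV must have columns: ",
                 paste(needed, collapse = ", "))
  }
  attr(tr, "n_prebleach") <- as.integer(n_prebleach)
  tr
}
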