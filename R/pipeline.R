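#' Assemble and validate a pipeline run configuration
#'
#' Collects acquisition settings, filter thresholds and bootstrap settings
#' with the working defaults used throughout: 300 nm linking radius, 1-frame
#' memory, 4-frame fragment gap, PSF thresholds (170, 215) nm, the
#' per-interval minimum-localization map, 10,000 BCa bootstrap samples.
#'
#' @param settings An [acquisition_settings()] object.
#' @param radius Linking radius, nm.
#' @param memory Linking memory, frames.
#' @param fragment_link Merge track fragments (enable for long-lived
#'   species).
#' @param max_gap Fragment-link gap, frames.
#' @param psf_threshold_x,psf_threshold_y Immobile-filter thresholds, nm;
#'   `NULL` derives the x threshold from the PSF mixture fit
#'   (mean + 2 sd of the bound component).
#' @param min_localizations Optional override of the per-interval map.
#' @param gmm_components 2, 3 or NULL (BIC auto-selection).
#' @param n_boot,bootstrap_method,seed Bootstrap settings.
#' @param grid_correction Frame-quantization-aware MLE (default TRUE).
#' @param constrained Use the joint constrained fit (near-bleach-limited
#'   binders).
#' @param bound_time_bounds,bleach_variation Constraints for
#'   [constrained_fit()] / [fit_two_exponential()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(settings,
                       radius = 300, memory = 1L,
                       fragment_link = FALSE, max_gap = 4L,
                       psf_threshold_x = 170, psf_threshold_y = 215,
                       min_localizations = NULL,
                       gmm_components = 2L,
                       n_boot = 10000L, bootstrap_method = "bca",
                       seed = 1L,
                       grid_correction = TRUE,
                       constrained = FALSE,
                       bound_time_bounds = c(1, 5400),
                       bleach_variation = 0.20) {
  stopifnot(inherits(settings, "acquisition_settings"))
  structure(
    list(settings = settings, radius = radius, memory = as.integer(memory),
         fragment_link = fragment_link, max_gap = as.integer(max_gap),
         psf_threshold_x = psf_threshold_x, psf_threshold_y = psf_threshold_y,
         min_localizations = min_localizations,
         gmm_components = gmm_components,
         n_boot = as.integer(n_boot), bootstrap_method = bootstrap_method,
         seed = as.integer(seed), grid_correction = grid_correction,
         constrained = constrained, bound_time_bounds = bound_time_bounds,
         bleach_variation = bleach_variation),
    class = "run_config"
  )
}

.stage <- function(log, name, n) {
  log[[length(log) + 1L]] <- list(stage = name, n = n)
  log
}

#' Run the sptPALM dwell-time pipeline
#'
#' Composes the full analysis on one or more localization tables plus a
#' bleach-control duration sample: link localizations, optionally merge
#' fragments, filter immobile tracks by PSF, apply the minimum-localization
#' threshold, isolate single-molecule tracks by intensity GMM, amalgamate
#' durations, fit the left-truncated exponential with bleach correction,
#' bootstrap errors, and run single- versus two-exponential model
#' selection.
#'
#' @param tables A localization table or list of tables (amalgamated as
#'   same-day, same-interval samples).
#' @param control A [track_duration_sample()] from a stable binder, or a
#'   ready [calibrate_bleach()] result.
#' @param config A [run_config()].
#' @param label Dataset label for the report.
#' @param report_path Optional path for a JSON report.
#' @return A list of class `dwell_report`: `estimate`
#'   (`bound_time_estimate`), `selection` (`model_selection`), `sample`,
#'   `calibration`, `stage_log`, `config_hash`, `seed`, `version`.
#' @export
run_dwell_pipeline <- function(tables, control, config, label = "",
                               report_path = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.data.frame(tables)) tables <- list(tables)
  if (length(tables) == 0L || any(!vapply(tables, is.data.frame, logical(1))) ||
      any(vapply(tables, nrow, integer(1)) == 0L)) {
    stop_invalid("empty input: need at least one non-empty localization table")
  }
  log <- list()
  durations <- numeric(0)
  truncation <- NA_real_
  for (tab in tables) {
    tracks <- link_localizations(tab, radius = config$radius,
                                 memory = config$memory,
                                 interval_time = config$settings$interval_time)
    log <- .stage(log, "link", length(unique(tracks$track_id)))
    if (config$fragment_link) {
      tracks <- link_track_fragments(tracks, max_gap = config$max_gap,
                                     radius = config$radius)
      log <- .stage(log, "fragment_link", length(unique(tracks$track_id)))
    }
    thr_x <- config$psf_threshold_x
    if (is.null(thr_x)) {
      psf_fit <- fit_psf_mixture(tab$sigma_x_nm)
      thr_x <- psf_threshold(psf_fit)
    }
    thr_y <- config$psf_threshold_y
    if (is.null(thr_y)) {
      psf_fit_y <- fit_psf_mixture(tab$sigma_y_nm)
      thr_y <- psf_threshold(psf_fit_y)
    }
    tracks <- filter_immobile(tracks, threshold_x = thr_x,
                              threshold_y = thr_y)
    log <- .stage(log, "immobile_filter", length(unique(tracks$track_id)))
    thresh <- apply_min_localization_threshold(
      tracks, interval_time = config$settings$interval_time,
      min_localizations = config$min_localizations)
    tracks <- thresh$tracks
    truncation <- thresh$truncation_point
    log <- .stage(log, "min_localizations", length(unique(tracks$track_id)))
    gmm <- fit_intensity_gmm(tracks, n_components = config$gmm_components)
    tracks <- gmm$tracks
    log <- .stage(log, "intensity_gmm", length(unique(tracks$track_id)))
    durations <- c(durations, track_summary(tracks)$duration)
  }
  if (length(durations) < 2L) {
    stop_invalid("pipeline stage 'amalgamate': fewer than 2 accepted tracks")
  }
  sample <- track_duration_sample(durations, truncation, config$settings,
                                  label = label)
  calibration <- if (inherits(control, "bleach_calibration")) control else
    calibrate_bleach(control, grid_correction = config$grid_correction)

  estimate <- if (config$constrained) {
    constrained_fit(sample, calibration,
                    bound_time_bounds = config$bound_time_bounds,
                    bleach_variation = config$bleach_variation,
                    likelihood = if (config$grid_correction) "grid" else
                      "continuous")
  } else {
    bootstrap_estimate(sample, calibration, n_boot = config$n_boot,
                       method = config$bootstrap_method, seed = config$seed,
                       grid_correction = config$grid_correction)
  }
  single <- constrained_fit(sample, calibration,
                            bound_time_bounds = config$bound_time_bounds,
                            bleach_variation = config$bleach_variation,
                            likelihood = if (config$grid_correction) "grid"
                            else "continuous")
  two <- tryCatch(
    fit_two_exponential(sample, calibration,
                        bleach_variation = config$bleach_variation,
                        likelihood = if (config$grid_correction) "grid" else
                          "continuous"),
    error = function(e) NULL)
  selection <- if (is.null(two)) NULL else select_model(single, two)

  report <- structure(
    list(estimate = estimate, selection = selection, sample = sample,
         calibration = calibration, stage_log = log,
         config_hash = rlang::hash(config), seed = config$seed,
         version = as.character(utils::packageVersion("replikinetics")),
         label = label),
    class = "dwell_report"
  )
  if (!is.null(report_path)) write_dwell_report(report, report_path)
  report
}

#' Serialize a dwell report to JSON
#'
#' @param report A `dwell_report`.
#' @param path Output path.
#' @export
write_dwell_report <- function(report, path) {
  est <- report$estimate
  out <- list(
    label = report$label,
    tau_track = est$T_track, T_bleach = est$T_bleach, T_bound = est$T_bound,
    se = est$se, ci95 = est$ci95, n = est$n,
    model_choice = if (is.null(report$selection)) NA else
      report$selection$choice,
    diagnostics = list(
      stage_log = report$stage_log,
      llr_p_value = if (is.null(report$selection)) NA else
        report$selection$llr_p_value,
      at_bound = est$at_bound %||% NA,
      n_dropped = est$n_dropped %||% 0L
    ),
    seed = report$seed, config_hash = report$config_hash,
    version = report$version
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the FRAP pipeline
#'
#' Filter traces, normalize to the pre-bleach mean, correct for acquisition
#' photobleaching (when control foci are present), collate into a mean
#' recovery curve, and fit the reaction-limited model with bootstrap
#' errors.
#'
#' @param traces Focus traces (plus optional `cell` and `control_focus`
#'   rows).
#' @param config A [run_config()] (only `n_boot` and `seed` are used here).
#' @param label Dataset label.
#' @param report_path Optional JSON report path.
#' @return A list of class `frap_report`: `fit` (`frap_fit`),
#'   `max_recovery`, `mean_trace`, `stage_log`, `config_hash`, `seed`,
#'   `version`.
#' @export
run_frap_pipeline <- function(traces, config, label = "",
                              report_path = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (nrow(traces[traces$roi_type == "focus", , drop = FALSE]) == 0L) {
    stop_invalid("empty input: no focus traces")
  }
  log <- list()
  foc <- filter_traces(traces)
  log <- .stage(log, "filter", length(unique(foc$cell_id)))
  if (nrow(foc) == 0L) stop_invalid("pipeline stage 'filter': no traces ",
                                    "survived the bleach-quality filters")
  # acquisition-bleaching correction is applied before normalization so
  # that corrected pre-bleach means are exactly 1 and the fitted recovery
  # parameters are on the undistorted scale
  has_control <- any(traces$roi_type == "control_focus")
  cells <- traces[traces$roi_type == "cell", , drop = FALSE]
  if (has_control) {
    ctrl <- normalize_trace(traces[traces$roi_type == "control_focus", ,
                                   drop = FALSE])
    baseline <- fit_bleach_baseline(ctrl)
    foc <- correct_photobleach(foc, baseline)
    if (nrow(cells) > 0L) cells <- correct_photobleach(cells, baseline)
    log <- .stage(log, "bleach_correct", length(unique(foc$cell_id)))
  } else baseline <- NULL
  foc <- normalize_trace(foc)
  max_rec <- if (nrow(cells) > 0L) estimate_max_recovery(cells) else 1
  mean_trace <- average_and_collate(foc)
  log <- .stage(log, "collate", nrow(mean_trace))
  fit <- fit_recovery(mean_trace, max_recovery = max_rec, traces = foc,
                      n_boot = config$n_boot, seed = config$seed)
  report <- structure(
    list(fit = fit, max_recovery = max_rec, mean_trace = mean_trace,
         baseline = baseline, stage_log = log,
         config_hash = rlang::hash(config), seed = config$seed,
         version = as.character(utils::packageVersion("replikinetics")),
         label = label),
    class = "frap_report"
  )
  if (!is.null(report_path)) {
    out <- list(label = label, c = fit$c, a = fit$a, b = fit$b,
                bound_time = fit$bound_time, se = as.list(fit$se),
                ci95 = fit$ci95, max_recovery = max_rec, ks_p = fit$ks_p,
                status = fit$status, stage_log = log, seed = config$seed,
                config_hash = report$config_hash, version = report$version)
    jsonlite::write_json(out, report_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  report
}
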