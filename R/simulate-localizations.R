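#' Generate a synthetic localization table
#'
#' Emulates the per-frame localization output of a motion-blur sptPALM
#' experiment. Bound molecules appear as runs of localizations at a fixed
#' position (plus localization noise) with narrow PSFs and optional blink
#' gaps; diffusing molecules appear as spatially scattered localizations
#' with blurred (wide) PSFs. Foci can carry one or two molecules, giving the
#' single/double intensity populations separated downstream by the
#' intensity GMM.
#'
#' @param params A [track_sim_params()] object (bound-molecule kinetics).
#' @param settings An [acquisition_settings()] object.
#' @param mixture A [mixture_spec()] describing PSF and intensity
#'   populations.
#' @param clip_blink_gaps_to Optional maximum blink-gap length in frames;
#'   gaps longer than this are clipped (useful to disable memory-exceeding
#'   gaps in controlled tests). Default `Inf` (no clipping).
#' @return A data.frame with columns `frame` (0-based), `x_nm`, `y_nm`,
#'   `sigma_x_nm`, `sigma_y_nm`, `intensity`, `background`, sorted by
#'   frame, with attributes `truth` (per-row molecule id and labels),
#'   `settings` and `mixture`.
#' @export
gen_localization_table <- function(params, settings, mixture,
                                   clip_blink_gaps_to = Inf) {
  stopifnot(inherits(params, "track_sim_params"),
            inherits(settings, "acquisition_settings"))
  if (!inherits(mixture, "mixture_spec")) {
    stop_invalid("`mixture` must be a mixture_spec object")
  }
  with_seed(params$seed, {
    rows <- list()
    truth <- list()
    mol_id <- 0L

    ## bound molecules ------------------------------------------------------
    frames_visible <- .simulate_frame_counts(params, settings)
    n_bound <- params$n_molecules
    pos_x <- stats::runif(n_bound, 0, mixture$field_size_nm)
    pos_y <- stats::runif(n_bound, 0, mixture$field_size_nm)
    is_multi <- stats::runif(n_bound) < mixture$multi_fraction
    blinks <- stats::runif(n_bound) < params$blink_probability
    for (i in seq_len(n_bound)) {
      n_vis <- frames_visible[i]
      if (n_vis < 1L) next
      present <- seq_len(n_vis)
      if (blinks[i] && n_vis > 2L) {
        n_events <- stats::rgeom(1L, prob = 1 / params$mean_blink_events) + 1L
        for (ev in seq_len(n_events)) {
          gap <- stats::rexp(1L, rate = 1 / params$blink_time_constant)
          missed <- min(floor(gap / settings$interval_time),
                        clip_blink_gaps_to)
          if (missed >= 1L) {
            at <- sample(2:(n_vis - 1L), 1L)
            present <- setdiff(present, seq(at, min(at + missed - 1L,
                                                    n_vis - 1L)))
          }
        }
      }
      m <- length(present)
      if (m == 0L) next
      mol_id <- mol_id + 1L
      level_mean <- if (is_multi[i]) mixture$intensity_multi_mean else
        mixture$intensity_single_mean
      level_sd <- if (is_multi[i]) mixture$intensity_multi_sd else
        mixture$intensity_single_sd
      rows[[mol_id]] <- data.frame(
        frame = present - 1L,
        x_nm = pos_x[i] + stats::rnorm(m, 0, mixture$localization_noise_sd),
        y_nm = pos_y[i] + stats::rnorm(m, 0, mixture$localization_noise_sd),
        sigma_x_nm = pmax(stats::rnorm(m, mixture$bound_psf_mean,
                                       mixture$bound_psf_sd), 1),
        sigma_y_nm = pmax(stats::rnorm(m, mixture$bound_psf_mean,
                                       mixture$bound_psf_sd), 1),
        intensity = pmax(stats::rnorm(m, level_mean, level_sd), 1),
        background = stats::rnorm(m, mixture$background_mean,
                                  mixture$background_sd)
      )
      truth[[mol_id]] <- data.frame(
        molecule = rep.int(mol_id, m),
        kind = rep("bound", m),
        multi = rep(is_multi[i], m)
      )
    }

    ## diffusing molecules --------------------------------------------------
    if (mixture$n_diffusing > 0L) {
      for (j in seq_len(mixture$n_diffusing)) {
        m <- min(stats::rgeom(1L, prob = 1 / mixture$diffusing_mean_frames)
                 + 1L, settings$n_frames)
        start <- sample.int(max(settings$n_frames - m + 1L, 1L), 1L) - 1L
        mol_id <- mol_id + 1L
        rows[[mol_id]] <- data.frame(
          frame = start + seq_len(m) - 1L,
          x_nm = stats::runif(m, 0, mixture$field_size_nm),
          y_nm = stats::runif(m, 0, mixture$field_size_nm),
          sigma_x_nm = pmax(stats::rnorm(m, mixture$diff_psf_mean,
                                         mixture$diff_psf_sd), 1),
          sigma_y_nm = pmax(stats::rnorm(m, mixture$diff_psf_mean,
                                         mixture$diff_psf_sd), 1),
          intensity = pmax(stats::rnorm(m, mixture$intensity_single_mean,
                                        mixture$intensity_single_sd), 1),
          background = stats::rnorm(m, mixture$background_mean,
                                    mixture$background_sd)
        )
        truth[[mol_id]] <- data.frame(
          molecule = rep.int(mol_id, m),
          kind = rep("diffusing", m),
          multi = rep(FALSE, m)
        )
      }
    }

    tab <- do.call(rbind, rows)
    tru <- do.call(rbind, truth)
    ord <- order(tab$frame, seq_len(nrow(tab)))
    tab <- tab[ord, , drop = FALSE]
    tru <- tru[ord, , drop = FALSE]
    rownames(tab) <- rownames(tru) <- NULL
    attr(tab, "truth") <- tru
    attr(tab, "settings") <- settings
    attr(tab, "mixture") <- mixture
    tab
  })
}

#' Write / read a localization table as CSV with a JSON ground-truth sidecar
#'
#' The CSV dialect has one row per localization with columns `frame`
#' (0-based), `x_nm`, `y_nm`, `sigma_x_nm`, `sigma_y_nm`, `intensity`,
#' `background`. When the table carries generator ground truth it is written
#' to `<path>.truth.json`.
#'
#' @param table A localization table.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_localization_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  tru <- attr(table, "truth")
  if (!is.null(tru)) {
    jsonlite::write_json(tru, paste0(path, ".truth.json"), digits = NA)
  }
  invisible(path)
}

#' @rdname write_localization_table
#' @export
read_localization_table <- function(path) {
  tab <- utils::read.csv(path)
  needed <- c("frame", "x_nm", "y_nm", "sigma_x_nm", "sigma_y_nm",
              "intensity", "background")
  if (!all(needed %in% names(tab))) {
    stop_invalid("localization CSV must have columns: ",
                 paste(needed, collapse = ", "))
  }
  side <- paste0(path, ".truth.json")
  if (file.exists(side)) {
    attr(tab, "truth") <- as.data.frame(jsonlite::read_json(
      side, simplifyVector = TRUE))
  }
  tab
}
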