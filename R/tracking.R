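#' Link localizations into single-molecule tracks
#'
#' Nearest-neighbour linking: localizations in consecutive frames are joined
#' into a track when they lie within `radius` of each other; a memory
#' parameter lets a molecule go dark for up to `memory` frames (blinking or
#' missed detection) and still be linked. Conflicts are resolved greedily by
#' ascending distance, ties by lower localization index.
#'
#' @param table Localization table (see [gen_localization_table()] for the
#'   column contract), sorted by frame.
#' @param radius Linking radius in nm (default 300).
#' @param memory Number of frames a molecule may go missing and still be
#'   linked (default 1).
#' @param interval_time Interval time in seconds; taken from the table's
#'   `settings` attribute when absent.
#' @return The table with a `track_id` column, class `tracks`; attributes
#'   `interval_time`, `radius`, `memory` and any generator `truth` are
#'   carried along.
#' @export
link_localizations <- function(table, radius = 300, memory = 1L,
                               interval_time = NULL) {
  check_positive(radius, "radius")
  if (memory < 0) stop_invalid("`memory` must be >= 0")
  if (is.unsorted(table$frame)) {
    stop_invalid("localization table must be sorted by frame")
  }
  if (is.null(interval_time)) {
    st <- attr(table, "settings")
    if (is.null(st)) stop_invalid("`interval_time` required when the table ",
                                  "carries no acquisition settings")
    interval_time <- st$interval_time
  }

  n <- nrow(table)
  track_id <- integer(n)
  # active track heads: id, x, y, last frame
  act_id <- integer(0); act_x <- numeric(0); act_y <- numeric(0)
  act_f <- integer(0)
  next_id <- 1L

  frames <- unique(table$frame)
  idx_by_frame <- split(seq_len(n), factor(table$frame, levels = frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    keep <- act_f >= f - 1L - memory & act_f < f
    act_id <- act_id[keep]; act_x <- act_x[keep]; act_y <- act_y[keep]
    act_f <- act_f[keep]
    rows <- idx_by_frame[[fi]]
    lx <- table$x_nm[rows]; ly <- table$y_nm[rows]
    assigned_loc <- rep(FALSE, length(rows))
    if (length(act_id) > 0L && length(rows) > 0L) {
      d <- sqrt(outer(act_x, lx, "-")^2 + outer(act_y, ly, "-")^2)
      cand <- which(d <= radius, arr.ind = TRUE)
      if (nrow(cand) > 0L) {
        ord <- order(d[cand], cand[, 2L])
        cand <- cand[ord, , drop = FALSE]
        track_free <- rep(TRUE, length(act_id))
        for (k in seq_len(nrow(cand))) {
          ti <- cand[k, 1L]; lj <- cand[k, 2L]
          if (track_free[ti] && !assigned_loc[lj]) {
            track_free[ti] <- FALSE
            assigned_loc[lj] <- TRUE
            track_id[rows[lj]] <- act_id[ti]
            act_x[ti] <- lx[lj]; act_y[ti] <- ly[lj]; act_f[ti] <- f
          }
        }
      }
    }
    new <- which(!assigned_loc)
    if (length(new) > 0L) {
      ids <- next_id + seq_along(new) - 1L
      next_id <- next_id + length(new)
      track_id[rows[new]] <- ids
      act_id <- c(act_id, ids)
      act_x <- c(act_x, lx[new]); act_y <- c(act_y, ly[new])
      act_f <- c(act_f, rep.int(f, length(new)))
    }
  }

  out <- as.data.frame(table)
  out$track_id <- track_id
  attr(out, "truth") <- attr(table, "truth")
  attr(out, "interval_time") <- interval_time
  attr(out, "radius") <- radius
  attr(out, "memory") <- memory
  class(out) <- c("tracks", "data.frame")
  out
}

#' Per-track summary statistics
#'
#' @param tracks A `tracks` object from [link_localizations()].
#' @return A data.frame with one row per track: `track_id`, `start_frame`,
#'   `end_frame`, `n_localizations`, means of position, PSF widths and
#'   intensity, and `duration` in seconds
#'   (`n_localizations * interval_time`).
#' @export
track_summary <- function(tracks) {
  interval <- attr(tracks, "interval_time")
  ids <- sort(unique(tracks$track_id))
  g <- factor(tracks$track_id, levels = ids)
  agg <- function(v, fun) as.numeric(tapply(v, g, fun))
  out <- data.frame(
    track_id = ids,
    start_frame = as.integer(tapply(tracks$frame, g, min)),
    end_frame = as.integer(tapply(tracks$frame, g, max)),
    n_localizations = as.integer(tapply(tracks$frame, g, length)),
    mean_x = agg(tracks$x_nm, mean),
    mean_y = agg(tracks$y_nm, mean),
    mean_sigma_x = agg(tracks$sigma_x_nm, mean),
    mean_sigma_y = agg(tracks$sigma_y_nm, mean),
    mean_intensity = agg(tracks$intensity, mean)
  )
  out$duration <- out$n_localizations * interval
  attr(out, "interval_time") <- interval
  out
}

.subset_tracks <- function(tracks, keep_ids) {
  keep <- tracks$track_id %in% keep_ids
  out <- tracks[keep, , drop = FALSE]
  tru <- attr(tracks, "truth")
  if (!is.null(tru)) attr(out, "truth") <- tru[keep, , drop = FALSE]
  for (a in c("interval_time", "radius", "memory")) {
    attr(out, a) <- attr(tracks, a)
  }
  class(out) <- class(tracks)
  out
}

#' Merge track fragments of long-lived molecules
#'
#' Long tracks of slowly bleaching, stably bound molecules fragment when the
#' detection software misses the focus for several frames. Fragments are
#' merged when their mean positions are at most `radius` apart and the gap
#' between them is at most `max_gap` frames; merging proceeds in frame order
#' to a fixed point.
#'
#' @param tracks A `tracks` object.
#' @param max_gap Maximum number of missing frames between fragments
#'   (default 4).
#' @param radius Maximum distance between fragment mean positions, nm.
#' @return A `tracks` object with merged `track_id`s.
#' @export
link_track_fragments <- function(tracks, max_gap = 4L, radius = 300) {
  if (max_gap < 0) stop_invalid("`max_gap` must be >= 0")
  repeat {
    s <- track_summary(tracks)
    s <- s[order(s$start_frame, s$track_id), , drop = FALSE]
    merged <- FALSE
    for (i in seq_len(nrow(s))) {
      gap <- s$start_frame - s$end_frame[i] - 1L
      dist <- sqrt((s$mean_x - s$mean_x[i])^2 + (s$mean_y - s$mean_y[i])^2)
      cand <- which(gap >= 0L & gap <= max_gap & dist <= radius)
      if (length(cand) > 0L) {
        j <- cand[order(gap[cand], dist[cand])][1L]
        tracks$track_id[tracks$track_id == s$track_id[j]] <- s$track_id[i]
        merged <- TRUE
        break
      }
    }
    if (!merged) return(tracks)
  }
}

#' Keep immobile tracks by mean PSF width
#'
#' Diffusing molecules are motion-blurred into wide PSFs; bound molecules
#' keep a diffraction-limited PSF. Tracks are retained when the mean PSF sd
#' over the track satisfies `mean_sigma_x <= threshold_x` and
#' `mean_sigma_y <= threshold_y`. Default thresholds are the working values
#' 170 nm (x) and 215 nm (y); a data-driven alternative is
#' [psf_threshold()].
#'
#' @param tracks A `tracks` object.
#' @param threshold_x,threshold_y Thresholds in nm.
#' @return The filtered `tracks` object.
#' @export
filter_immobile <- function(tracks, threshold_x = 170, threshold_y = 215) {
  check_positive(threshold_x, "threshold_x")
  check_positive(threshold_y, "threshold_y")
  s <- track_summary(tracks)
  keep <- s$track_id[s$mean_sigma_x <= threshold_x &
                       s$mean_sigma_y <= threshold_y]
  .subset_tracks(tracks, keep)
}

#' Remove short tracks and record the truncation point
#'
#' Tracks with fewer localizations than the per-interval acceptance
#' threshold are discarded; the truncation point
#' `L = min_localizations * interval_time` is returned for the downstream
#' left-truncated MLE.
#'
#' @param tracks A `tracks` object.
#' @param interval_time Interval time in seconds (default: the tracks'
#'   attribute).
#' @param min_localizations Optional explicit threshold override.
#' @return A list with `tracks` (kept tracks) and `truncation_point`
#'   (seconds).
#' @export
apply_min_localization_threshold <- function(tracks, interval_time = NULL,
                                             min_localizations = NULL) {
  if (is.null(interval_time)) interval_time <- attr(tracks, "interval_time")
  min_loc <- min_localizations_for(interval_time,
                                   min_localizations = min_localizations)
  s <- track_summary(tracks)
  keep <- s$track_id[s$n_localizations >= min_loc]
  list(tracks = .subset_tracks(tracks, keep),
       truncation_point = min_loc * interval_time)
}

#' Durations of accepted tracks as a sample for dwell-time inference
#'
#' Convenience bridge from the tracking stage to the dwell-time stage.
#'
#' @param tracks A `tracks` object (already thresholded).
#' @param truncation_point Truncation point L in seconds.
#' @param settings An [acquisition_settings()] object.
#' @param label Sample label.
#' @return A [track_duration_sample()].
#' @export
tracks_to_duration_sample <- function(tracks, truncation_point, settings,
                                      label = "") {
  s <- track_summary(tracks)
  track_duration_sample(s$duration, truncation_point, settings, label = label)
}

#' Gap times between consecutive binding events at the same position
#'
#' For each track end, finds the first later track starting within `radius`
#' of it and emits the intervening time, interpreting the new track as a
#' fresh binding (rebinding) event at the same site. No minimum-localization
#' threshold is applied here.
#'
#' @param tracks A `tracks` object.
#' @param radius Matching radius in nm (default 300).
#' @param interval_time Interval time in seconds (default: attribute).
#' @return Numeric vector of gap times in seconds.
#' @export
detect_rebinding <- function(tracks, radius = 300, interval_time = NULL) {
  if (is.null(interval_time)) interval_time <- attr(tracks, "interval_time")
  s <- track_summary(tracks)
  s <- s[order(s$start_frame, s$track_id), , drop = FALSE]
  gaps <- numeric(0)
  for (i in seq_len(nrow(s))) {
    later <- which(s$start_frame > s$end_frame[i])
    if (length(later) == 0L) next
    dist <- sqrt((s$mean_x[later] - s$mean_x[i])^2 +
                   (s$mean_y[later] - s$mean_y[i])^2)
    hit <- later[dist <= radius]
    if (length(hit) == 0L) next
    j <- hit[which.min(s$start_frame[hit])]
    gaps <- c(gaps, (s$start_frame[j] - s$end_frame[i]) * interval_time)
  }
  gaps
}
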