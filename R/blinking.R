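#' Fit the photoblinking gap-time model
#'
#' Dark gaps between consecutive appearances of a bound molecule at the same
#' position (measured at near-continuous acquisition) are modelled as
#' exponential. Gaps shorter than one exposure cannot be observed, and gaps
#' longer than `cutoff` (default 2.6 s, from the characterization of the
#' mMaple fluorophore) are treated as new binding events rather than blinks,
#' so the time constant is the MLE of an exponential doubly truncated to
#' `[exposure, cutoff]`.
#'
#' @param gap_times Observed gap durations in seconds.
#' @param exposure Exposure (= interval) time of the acquisition, seconds.
#' @param cutoff Maximum blink duration, seconds (default 2.6).
#' @param blink_fraction Fraction of molecules that blink at all (scales the
#'   premature-termination probability; default 1 is conservative).
#' @param memory Tracking memory in frames the model will be evaluated
#'   against (default 1).
#' @return An object of class `blink_model`: `gap_time_constant`,
#'   `blink_fraction`, `cutoff`, `memory`, `n_gaps`, `log_likelihood`.
#' @export
analyze_blinking <- function(gap_times, exposure, cutoff = 2.6,
                             blink_fraction = 1, memory = 1L) {
  check_positive(exposure, "exposure")
  check_positive(cutoff, "cutoff")
  check_fraction(blink_fraction, "blink_fraction")
  gaps <- gap_times[gap_times <= cutoff]
  if (length(gaps) == 0L) {
    stop_invalid("no gaps below the ", cutoff, " s cutoff: all observed ",
                 "gaps look like new binding events, not blinks")
  }
  if (any(gaps < exposure)) {
    stop_invalid("gaps shorter than one exposure are unobservable; check ",
                 "the input units")
  }
  L <- exposure; U <- cutoff
  nll <- function(tau) {
    sum(log(tau) + (gaps - L) / tau + log(1 - exp(-(U - L) / tau)))
  }
  opt <- stats::optimize(nll, interval = c(1e-3, 1e3))
  structure(
    list(gap_time_constant = opt$minimum, blink_fraction = blink_fraction,
         cutoff = cutoff, memory = as.integer(memory),
         n_gaps = length(gaps), log_likelihood = -opt$objective),
    class = "blink_model"
  )
}

#' @export
print.blink_model <- function(x, ...) {
  cat(sprintf("Blink model: gap time constant %.3g s (n = %d gaps <= %.2g s)\n",
              x$gap_time_constant, x$n_gaps, x$cutoff))
  invisible(x)
}

#' Probability that blinking prematurely terminates a track
#'
#' Under the fitted gap model, a track is lost when a blink gap outlasts the
#' memory window `memory * interval`; the exponential tail probability is
#' scaled by the fraction of molecules that blink. Decreases monotonically
#' with interval time, which is why long-interval protocols are robust to
#' blinking.
#'
#' @param model A [analyze_blinking()] fit (or any list with
#'   `gap_time_constant` and `blink_fraction`).
#' @param interval Interval time in seconds.
#' @param memory Tracking memory in frames (default: the model's).
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' m <- list(gap_time_constant = 0.386, blink_fraction = 1, memory = 1L)
#' premature_termination_probability(m, interval = 1)  # ~0.075
premature_termination_probability <- function(model, interval,
                                              memory = NULL) {
  check_positive(interval, "interval")
  if (is.null(memory)) memory <- model$memory %||% 1L
  window <- memory * interval
  model$blink_fraction * exp(-window / model$gap_time_constant)
}
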