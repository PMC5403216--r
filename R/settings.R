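#' Acquisition settings for an sptPALM experiment
#'
#' Bundles the camera timing used both by the synthetic-data generators and
#' by the dwell-time analysis. The interval/exposure ratio (duty cycle)
#' rescales the effective photobleaching time: a fluorophore only bleaches
#' while the shutter is open, so stroboscopic protocols (e.g. 500 ms
#' exposures spaced by 1 s or 5 s) extend the apparent bleach lifetime by
#' `interval_time / exposure_time`.
#'
#' @param exposure_time Camera exposure per frame, seconds.
#' @param interval_time Time between frame starts, seconds; must be at least
#'   `exposure_time`. Defaults to continuous acquisition
#'   (`interval_time == exposure_time`).
#' @param n_frames Number of frames in the acquisition.
#' @param pixel_size Pixel size in nm (metadata only; positions are stored
#'   in nm throughout).
#' @return An object of class `acquisition_settings`.
#' @export
#' @examples
#' acquisition_settings(exposure_time = 0.5, interval_time = 1, n_frames = 600)
acquisition_settings <- function(exposure_time, interval_time = exposure_time,
                                 n_frames = 600L, pixel_size = 100) {
  check_positive(exposure_time, "exposure_time")
  check_positive(interval_time, "interval_time")
  if (interval_time < exposure_time) {
    stop_invalid("`interval_time` must be >= `exposure_time`")
  }
  if (!is.numeric(n_frames) || n_frames < 1) {
    stop_invalid("`n_frames` must be >= 1")
  }
  structure(
    list(exposure_time = exposure_time, interval_time = interval_time,
         n_frames = as.integer(n_frames), pixel_size = pixel_size),
    class = "acquisition_settings"
  )
}

#' @export
print.acquisition_settings <- function(x, ...) {
  cat(sprintf("Acquisition: %g s exposure / %g s interval, %d frames\n",
              x$exposure_time, x$interval_time, x$n_frames))
  invisible(x)
}

#' Simulation parameters for synthetic track-duration data
#'
#' Ground-truth kinetics for the sptPALM generator. Binding durations are
#' exponential with mean `true_bound_time` (the reciprocal of the unbinding
#' rate k_off); photobleaching is exponential in accumulated exposure with
#' constant-exposure time `constant_exposure_bleach_time`. Photoblinking is
#' parameterised after the mMaple fluorophore: a molecule blinks with
#' probability `blink_probability`, the number of blink events is geometric
#' with mean `mean_blink_events`, and dark-gap durations are exponential
#' with mean `blink_time_constant`.
#'
#' @param true_bound_time Mean binding duration, seconds (`Inf` for a stable
#'   binder such as a LacI bleaching control).
#' @param constant_exposure_bleach_time Mean bleaching time under continuous
#'   exposure, seconds.
#' @param blink_probability Probability that a molecule blinks at all.
#' @param blink_time_constant Mean dark-gap duration, seconds.
#' @param mean_blink_events Mean number of blink events for a blinking
#'   molecule.
#' @param n_molecules Number of molecules to simulate.
#' @param seed Integer seed; identical seeds reproduce identical output.
#' @return An object of class `track_sim_params`.
#' @export
track_sim_params <- function(true_bound_time,
                             constant_exposure_bleach_time = 15,
                             blink_probability = 0.49,
                             blink_time_constant = 0.386,
                             mean_blink_events = 3.4,
                             n_molecules = 1000L,
                             seed = 1L) {
  if (!(is.numeric(true_bound_time) && length(true_bound_time) == 1L &&
        true_bound_time > 0)) {
    stop_invalid("`true_bound_time` must be positive (Inf allowed)")
  }
  check_positive(constant_exposure_bleach_time, "constant_exposure_bleach_time")
  check_fraction(blink_probability, "blink_probability")
  check_positive(blink_time_constant, "blink_time_constant")
  if (mean_blink_events < 1) stop_invalid("`mean_blink_events` must be >= 1")
  if (n_molecules < 1) stop_invalid("`n_molecules` must be >= 1")
  structure(
    list(true_bound_time = true_bound_time,
         constant_exposure_bleach_time = constant_exposure_bleach_time,
         blink_probability = blink_probability,
         blink_time_constant = blink_time_constant,
         mean_blink_events = mean_blink_events,
         n_molecules = as.integer(n_molecules),
         seed = as.integer(seed)),
    class = "track_sim_params"
  )
}

#' Simulation parameters for synthetic FRAP traces
#'
#' Ground truth for the reaction-limited recovery model
#' `y(t) = c - a exp(-b t)` (post-bleach), composed with a global
#' exponential photobleaching decay of the whole field.
#'
#' @param asymptote Recovery asymptote `c`, normalised units.
#' @param amplitude Recovery amplitude `a`, normalised units; the value at
#'   the bleach (t = 0) is `c - a`.
#' @param unbinding_rate Exchange rate `b` (k_off), per second.
#' @param global_bleach_time Time constant of acquisition photobleaching,
#'   seconds (`Inf` disables the decay).
#' @param noise_sd Gaussian noise sd on each intensity point.
#' @param n_prebleach Number of pre-bleach points (at negative times).
#' @param sample_times Strictly increasing sample times, seconds, with the
#'   bleach at t = 0; the first `n_prebleach` must be negative.
#' @param n_traces Number of per-focus traces to generate.
#' @param seed Integer seed.
#' @return An object of class `frap_sim_params`.
#' @export
frap_sim_params <- function(asymptote, amplitude, unbinding_rate,
                            global_bleach_time = Inf, noise_sd = 0.02,
                            n_prebleach = 2L,
                            sample_times = c(-10, -5, 0, 1, 2, 3, 5, 7, 10,
                                             15, 20, 30, 45, 60),
                            n_traces = 50L, seed = 1L) {
  check_positive(asymptote, "asymptote")
  check_positive(amplitude, "amplitude")
  check_positive(unbinding_rate, "unbinding_rate")
  if (!(amplitude <= asymptote && asymptote <= 1.1)) {
    stop_invalid("need 0 < amplitude <= asymptote <= 1.1")
  }
  if (noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")
  if (any(diff(sample_times) <= 0)) {
    stop_invalid("`sample_times` must be strictly increasing")
  }
  if (n_prebleach < 2 || any(sample_times[seq_len(n_prebleach)] >= 0)) {
    stop_invalid("need >= 2 pre-bleach points, all at negative times")
  }
  structure(
    list(asymptote = asymptote, amplitude = amplitude,
         unbinding_rate = unbinding_rate,
         global_bleach_time = global_bleach_time, noise_sd = noise_sd,
         n_prebleach = as.integer(n_prebleach), sample_times = sample_times,
         n_traces = as.integer(n_traces), seed = as.integer(seed)),
    class = "frap_sim_params"
  )
}

#' Mixture specification for synthetic localization tables
#'
#' Describes the bound-vs-diffusing PSF-width populations and the
#' single-vs-multi-molecule intensity populations used by
#' [gen_localization_table()]. Defaults reproduce the characteristic
#' bimodal PSF histogram of motion-blur sptPALM: immobile molecules near a
#' 100 nm PSF sd, diffusing molecules blurred to about 200 nm.
#'
#' @param bound_psf_mean,bound_psf_sd PSF sd distribution (nm) of bound
#'   molecules.
#' @param diff_psf_mean,diff_psf_sd PSF sd distribution (nm) of diffusing
#'   molecules.
#' @param intensity_single_mean,intensity_single_sd Mean-intensity
#'   distribution of single molecules (arbitrary units).
#' @param intensity_multi_mean,intensity_multi_sd Intensity distribution of
#'   multi-molecule (double) foci.
#' @param multi_fraction Fraction of bound foci that carry two molecules.
#' @param n_diffusing Number of diffusing molecules to scatter.
#' @param diffusing_mean_frames Mean number of frames a diffusing molecule
#'   stays visible (geometric).
#' @param background_mean,background_sd Background level distribution.
#' @param localization_noise_sd Localization precision (nm sd) applied to
#'   bound positions.
#' @param field_size_nm Side of the square field of view, nm.
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(bound_psf_mean = 100, bound_psf_sd = 15,
                         diff_psf_mean = 200, diff_psf_sd = 30,
                         intensity_single_mean = 1000,
                         intensity_single_sd = 150,
                         intensity_multi_mean = 2000,
                         intensity_multi_sd = 250,
                         multi_fraction = 0,
                         n_diffusing = 0L,
                         diffusing_mean_frames = 2,
                         background_mean = 50, background_sd = 5,
                         localization_noise_sd = 20,
                         field_size_nm = 40000) {
  for (nm in c("bound_psf_mean", "bound_psf_sd", "diff_psf_mean",
               "diff_psf_sd", "intensity_single_mean", "intensity_single_sd",
               "intensity_multi_mean", "intensity_multi_sd",
               "diffusing_mean_frames", "field_size_nm")) {
    check_positive(get(nm), nm)
  }
  check_fraction(multi_fraction, "multi_fraction")
  if (n_diffusing < 0) stop_invalid("`n_diffusing` must be >= 0")
  if (localization_noise_sd < 0) {
    stop_invalid("`localization_noise_sd` must be >= 0")
  }
  structure(
    list(bound_psf_mean = bound_psf_mean, bound_psf_sd = bound_psf_sd,
         diff_psf_mean = diff_psf_mean, diff_psf_sd = diff_psf_sd,
         intensity_single_mean = intensity_single_mean,
         intensity_single_sd = intensity_single_sd,
         intensity_multi_mean = intensity_multi_mean,
         intensity_multi_sd = intensity_multi_sd,
         multi_fraction = multi_fraction,
         n_diffusing = as.integer(n_diffusing),
         diffusing_mean_frames = diffusing_mean_frames,
         background_mean = background_mean, background_sd = background_sd,
         localization_noise_sd = localization_noise_sd,
         field_size_nm = field_size_nm),
    class = "mixture_spec"
  )
}

# Minimum number of localizations required for track acceptance, by interval
# time in seconds. Tracks shorter than the minimum are discarded, which is
# why downstream fitting uses a left-truncated model.
.default_min_localization_map <- c("1" = 4L, "2" = 3L, "5" = 2L, "10" = 2L)

#' Minimum-localization threshold for a given interval time
#'
#' Longer intervals make it likelier that a detected track is a genuinely
#' bound molecule, so the acceptance threshold relaxes with interval time.
#' Defaults: at least 4, 3, 2 and 2 localizations for 1 s, 2 s, 5 s and
#' 10 s intervals.
#'
#' @param interval_time Interval time in seconds.
#' @param map Named integer vector mapping interval (as character) to the
#'   minimum localization count.
#' @param min_localizations Optional explicit override.
#' @return Integer minimum number of localizations.
#' @export
min_localizations_for <- function(interval_time,
                                  map = .default_min_localization_map,
                                  min_localizations = NULL) {
  if (!is.null(min_localizations)) return(as.integer(min_localizations))
  key <- format(interval_time)
  if (!key %in% names(map)) {
    stop_invalid("no minimum-localization threshold configured for interval ",
                 interval_time, " s; pass `min_localizations` explicitly")
  }
  as.integer(map[[key]])
}
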