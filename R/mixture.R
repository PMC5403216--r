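#' Univariate Gaussian mixture fit by EM
#'
#' Maximum-likelihood fit of a k-component univariate Gaussian mixture via
#' expectation-maximisation. Initialisation places component means at
#' equally spaced sample quantiles (deterministic first start) followed by
#' random restarts; the best log-likelihood wins. Used for both the
#' PSF-width bound/diffusing split and the track-intensity
#' single/multi-molecule split.
#'
#' @param x Numeric data.
#' @param k Number of components.
#' @param n_restarts Number of EM starts (first is deterministic).
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Maximum EM iterations per start.
#' @return A list of class `gaussian_mixture`: `weight`, `mean`, `sd`
#'   (length-k, ordered by mean), `log_likelihood`, `bic`, `n_iter`,
#'   `loglik_trace`, `responsibilities` (n x k), `n_components`, `n`.
#' @export
fit_gaussian_mixture <- function(x, k = 2L, n_restarts = 10L, tol = 1e-8,
                                 max_iter = 1000L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L * k) stop_invalid("need at least ", 2L * k, " values")
  if (stats::sd(x) == 0) stop_invalid("degenerate input: all values equal")
  sd_floor <- 1e-4 * stats::sd(x)

  run_em <- function(mu, sg, w) {
    trace <- numeric(0)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      logd <- vapply(seq_len(k), function(j) {
        log(w[j]) + stats::dnorm(x, mu[j], sg[j], log = TRUE)
      }, numeric(n))
      m <- apply(logd, 1L, max)
      lse <- m + log(rowSums(exp(logd - m)))
      ll <- sum(lse)
      trace <- c(trace, ll)
      r <- exp(logd - lse)
      nk <- colSums(r)
      if (any(nk < 1e-10)) break
      w <- nk / n
      mu <- colSums(r * x) / nk
      sg <- pmax(sqrt(colSums(r * (x - rep(mu, each = n))^2) / nk), sd_floor)
      if (is.finite(ll_old) && ll - ll_old < tol) break
      ll_old <- ll
    }
    list(mu = mu, sg = sg, w = w, ll = ll, it = it, trace = trace, r = r)
  }

  qs <- stats::quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k),
                        names = FALSE)
  starts <- list(list(mu = qs, sg = rep(stats::sd(x) / k, k),
                      w = rep(1 / k, k)))
  if (n_restarts > 1L) {
    for (r in seq_len(n_restarts - 1L)) {
      starts[[r + 1L]] <- list(mu = sort(sample(x, k)),
                               sg = rep(stats::sd(x) / k, k),
                               w = rep(1 / k, k))
    }
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(run_em(s$mu, s$sg, s$w), error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$ll > best$ll)) best <- fit
  }
  if (is.null(best)) stop_invalid("EM failed to converge from any start")

  ord <- order(best$mu)
  n_par <- 3L * k - 1L
  structure(
    list(weight = best$w[ord], mean = best$mu[ord], sd = best$sg[ord],
         log_likelihood = best$ll,
         bic = -2 * best$ll + n_par * log(n),
         n_iter = best$it, loglik_trace = best$trace,
         responsibilities = best$r[, ord, drop = FALSE],
         n_components = k, n = n),
    class = "gaussian_mixture"
  )
}

#' @export
print.gaussian_mixture <- function(x, ...) {
  cat(sprintf("%d-component Gaussian mixture (n = %d, logLik = %.2f, BIC = %.2f)\n",
              x$n_components, x$n, x$log_likelihood, x$bic))
  print(data.frame(weight = round(x$weight, 3), mean = round(x$mean, 2),
                   sd = round(x$sd, 2)))
  invisible(x)
}

#' Two-component PSF-width mixture for the bound/diffusing split
#'
#' Fits the two-component Gaussian mixture
#' `p N(mu1, sigma1) + (1 - p) N(mu2, sigma2)` to per-localization PSF
#' standard deviations; the component with the smaller mean is labelled
#' "bound" (immobile molecules keep a diffraction-limited PSF; diffusing
#' molecules are motion-blurred to larger widths).
#'
#' @param values PSF sds in nm.
#' @param n_components Number of components (default 2).
#' @return A `gaussian_mixture` with an added `bound_component` element
#'   (index of the lower-mean component, always 1 after ordering).
#' @export
fit_psf_mixture <- function(values, n_components = 2L) {
  fit <- fit_gaussian_mixture(values, k = n_components)
  fit$bound_component <- 1L
  fit
}

#' Data-driven PSF acceptance threshold
#'
#' The bound-component mean plus `n_sd` standard deviations (default 2).
#'
#' @param fit A fit from [fit_psf_mixture()].
#' @param n_sd Number of sds above the bound-component mean.
#' @return Threshold in nm.
#' @export
psf_threshold <- function(fit, n_sd = 2) {
  j <- fit$bound_component
  fit$mean[j] + n_sd * fit$sd[j]
}

#' Isolate single-molecule tracks by mean intensity
#'
#' Fits a Gaussian mixture to per-track mean intensities and keeps the
#' cluster representing single molecules: the lowest-mean cluster for a
#' 2-component fit, or the second-lowest for a 3-component fit (the lowest
#' then being an out-of-focus low-intensity spike). With
#' `n_components = NULL` both models are fitted and the lower BIC wins.
#' Tracks are assigned to clusters by maximum membership probability.
#'
#' @param tracks A `tracks` object (or a [track_summary()] data.frame).
#' @param n_components 2, 3, or `NULL` for BIC-based auto-selection.
#' @return A list: `fit` (the chosen `gaussian_mixture`), `tracks` (the
#'   single-molecule subset, same class as the input), `single_cluster`
#'   (index), `assignment` (cluster per track), `summary` (per-track
#'   summary with `cluster` column), `bic` (named vector of candidate
#'   BICs).
#' @export
fit_intensity_gmm <- function(tracks, n_components = NULL) {
  s <- if (is.data.frame(tracks) && "mean_intensity" %in% names(tracks) &&
           !"intensity" %in% names(tracks)) tracks else track_summary(tracks)
  if (nrow(s) < 10L) stop_invalid("need at least 10 tracks for the ",
                                  "intensity GMM")
  if (!is.null(n_components) && !n_components %in% c(2L, 3L)) {
    stop_invalid("`n_components` must be 2, 3 or NULL")
  }
  ks <- if (is.null(n_components)) c(2L, 3L) else n_components
  fits <- lapply(ks, function(k) {
    tryCatch(fit_gaussian_mixture(s$mean_intensity, k = k),
             error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop_invalid("intensity GMM failed for all candidate models")
  bics <- vapply(fits[ok], `[[`, numeric(1), "bic")
  names(bics) <- paste0(ks[ok], "comp")
  fit <- fits[ok][[which.min(bics)]]
  single_cluster <- if (fit$n_components == 3L) 2L else 1L
  assignment <- max.col(fit$responsibilities)
  s$cluster <- assignment
  keep_ids <- s$track_id[assignment == single_cluster]
  out_tracks <- if (inherits(tracks, "tracks")) {
    .subset_tracks(tracks, keep_ids)
  } else {
    tracks[tracks$track_id %in% keep_ids, , drop = FALSE]
  }
  list(fit = fit, tracks = out_tracks, single_cluster = single_cluster,
       assignment = assignment, summary = s, bic = bics)
}
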