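#' Per-fork clamp-loading interval
#'
#' With `beta_dimers_per_fork` clamps resident at a fork and each remaining
#' bound for `beta_unload_time` seconds, steady state requires one new clamp
#' loaded every `beta_unload_time / beta_dimers_per_fork` seconds
#' (the effective loading rate is `beta_dimers_per_fork / beta_unload_time`).
#'
#' @param beta_dimers_per_fork Number of beta-clamp dimers per replication
#'   fork (the in vivo estimate is 23).
#' @param beta_unload_time Mean bound time of a clamp, seconds.
#' @return Loading interval in seconds.
#' @export
#' @examples
#' clamp_loading_interval(23, 47)  # ~2 s
clamp_loading_interval <- function(beta_dimers_per_fork, beta_unload_time) {
  if (beta_dimers_per_fork <= 0) stop_invalid("`beta_dimers_per_fork` must ",
                                              "be positive")
  check_positive(beta_unload_time, "beta_unload_time")
  beta_unload_time / beta_dimers_per_fork
}

#' Average replication-fork rate
#'
#' Genome size divided by the number of forks and the duration of
#' replication. Round in the report layer, not here.
#'
#' @param genome_size Genome size in bp (E. coli: 4.6e6).
#' @param n_forks Number of concurrent forks (2 for a single bidirectional
#'   replication event).
#' @param replication_time Replication duration in seconds.
#' @return Fork rate in bp per second.
#' @export
#' @examples
#' fork_rate(4.6e6, 2, 150 * 60)  # ~256 bp/s, reported as ~260
fork_rate <- function(genome_size, n_forks, replication_time) {
  check_positive(genome_size, "genome_size")
  check_positive(n_forks, "n_forks")
  check_positive(replication_time, "replication_time")
  genome_size / n_forks / replication_time
}

#' Average Okazaki fragment length
#'
#' One clamp is loaded per priming cycle, so fragment length is the
#' clamp-loading interval times the fork rate.
#'
#' @param loading_interval Clamp-loading interval in seconds.
#' @param fork_rate Fork rate in bp/s.
#' @return Length in bp.
#' @export
#' @examples
#' okazaki_length(2, 260)  # 520 bp
okazaki_length <- function(loading_interval, fork_rate) {
  if (loading_interval < 0) stop_invalid("`loading_interval` must be >= 0")
  check_positive(fork_rate, "fork_rate")
  loading_interval * fork_rate
}

#' DNA synthesized per polymerase exchange
#'
#' Fork rate times the polymerase bound time: how far a fork advances before
#' the polymerase subassembly is replaced.
#'
#' @param bound_time Polymerase bound time in seconds.
#' @param fork_rate Fork rate in bp/s.
#' @return Length in bp.
#' @export
#' @examples
#' synthesis_before_exchange(4, 260)   # ~1 kbp
#' synthesis_before_exchange(12, 260)  # ~3 kbp
synthesis_before_exchange <- function(bound_time, fork_rate) {
  if (bound_time < 0) stop_invalid("`bound_time` must be >= 0")
  check_positive(fork_rate, "fork_rate")
  bound_time * fork_rate
}

#' Replication-cycle report from kinetic estimates
#'
#' Chains the derived metrics. `rounded_chain = TRUE` reproduces the
#' headline arithmetic at one significant figure on the intermediate values
#' (loading interval ~2 s, fork rate ~260 bp/s giving 520 bp); the exact
#' chain keeps full precision.
#'
#' @param genome_size,n_forks,replication_time See [fork_rate()].
#' @param beta_dimers_per_fork,beta_unload_time See
#'   [clamp_loading_interval()].
#' @param pol_bound_time Optional polymerase bound time(s), seconds.
#' @param rounded_chain Use one-significant-figure intermediates (default
#'   TRUE, matching how the headline numbers are quoted).
#' @return A list with `loading_interval_s`, `fork_rate_bp_s`,
#'   `okazaki_length_bp` and optionally `synthesis_per_exchange_bp`.
#' @export
replication_report <- function(genome_size = 4.6e6, n_forks = 2,
                               replication_time = 150 * 60,
                               beta_dimers_per_fork = 23,
                               beta_unload_time = 47,
                               pol_bound_time = NULL,
                               rounded_chain = TRUE) {
  load_int <- clamp_loading_interval(beta_dimers_per_fork, beta_unload_time)
  rate <- fork_rate(genome_size, n_forks, replication_time)
  li <- if (rounded_chain) signif(load_int, 1) else load_int
  fr <- if (rounded_chain) signif(rate, 2) else rate
  out <- list(loading_interval_s = li, fork_rate_bp_s = fr,
              okazaki_length_bp = okazaki_length(li, fr),
              exact = list(loading_interval_s = load_int,
                           fork_rate_bp_s = rate,
                           okazaki_length_bp = okazaki_length(load_int, rate)))
  if (!is.null(pol_bound_time)) {
    out$synthesis_per_exchange_bp <- synthesis_before_exchange(
      pol_bound_time, fr)
  }
  out
}
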