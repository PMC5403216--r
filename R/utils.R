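#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so generator calls never perturb user RNG.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stop_invalid <- function(...) {
  stop(paste0(...), call. = FALSE)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop_invalid("`", name, "` must be a single positive number")
  }
  invisible(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_invalid("`", name, "` must lie in [0, 1]")
  }
  invisible(x)
}
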