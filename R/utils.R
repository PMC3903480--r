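# Internal helpers shared across the package.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never disturb user RNG flow.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive per-subject integer seed streams from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  invisible(x)
}

# Locate a time point on a grid, with tolerance of a tenth of a sample.
time_index <- function(times, t) {
  dt <- if (length(times) > 1L) times[2L] - times[1L] else 1
  i <- which(abs(times - t) < dt / 10)
  if (length(i) != 1L)
    stop(sprintf("time %g s is not on the time grid", t), call. = FALSE)
  i
}
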