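# Generative simulator: sensor-level generators with random projections.
#
# Each generator g carries a projection vector C_g (one coefficient per
# channel, drawn from a standard normal) and an activation profile A_g(t) that
# is 1 inside its active window and 0 outside. A trial of class y in {-1, +1}
# is S(c, t) = y * sum_g A_g(t) * s_g(t) * C_g(c) plus i.i.d. Gaussian noise,
# where s_g(t) is the class-coupling sign (+1 except in reversal scenarios).
# Sample indices in scenario definitions are 0-based; the active window of a
# generator with onset o and duration d is [o, o + d).

new_scenario <- function(generators, n_samples, kind) {
  for (g in generators) {
    if (g$onset < 0L || g$onset + g$duration > n_samples)
      stop(sprintf(
        "generator window [%d, %d) exceeds the %d available samples",
        g$onset, g$onset + g$duration, n_samples))
  }
  structure(list(generators = generators, n_samples = as.integer(n_samples),
                 kind = kind),
            class = "tg_scenario")
}

#' Sequential-generator scenario (serial dynamics)
#'
#' A chain of generators with abutting, non-overlapping active windows of
#' equal duration, emulating the serial recruitment of distinct neural
#' sources. Decoding such data yields a diagonal-shaped temporal
#' generalization matrix.
#'
#' @param n_generators number of generators (default 10).
#' @param duration active-window length of each generator, in samples
#'   (default 6).
#' @param start 0-based sample index at which the first generator switches on.
#' @param n_samples total samples per epoch the scenario is defined over.
#' @return A `tg_scenario`.
#' @export
sequential_scenario <- function(n_generators = 10L, duration = 6L,
                                start = 10L, n_samples = 80L) {
  if (n_generators < 1L) stop("n_generators must be >= 1")
  gens <- lapply(seq_len(n_generators) - 1L, function(i) {
    list(onset = as.integer(start + i * duration),
         duration = as.integer(duration),
         sign = rep(1, duration))
  })
  new_scenario(gens, n_samples, "sequential")
}

#' Single sustained-generator scenario (stable dynamics)
#'
#' One generator active throughout a long window, emulating a stable pattern
#' of activity; decoding yields a square temporal generalization matrix.
#' `duration = 0` gives a null scenario with no informative samples.
#'
#' @inheritParams sequential_scenario
#' @export
sustained_scenario <- function(duration = 60L, start = 10L, n_samples = 80L) {
  if (duration < 0L) stop("duration must be >= 0")
  gens <- if (duration == 0L) list() else
    list(list(onset = as.integer(start), duration = as.integer(duration),
              sign = rep(1, duration)))
  new_scenario(gens, n_samples, if (duration == 0L) "null" else "sustained")
}

#' Polarity-reversal scenario (below-chance generalization)
#'
#' One generator whose coupling to the class flips sign at `flip_at`: +1 over
#' `[start, flip_at)`, -1 over `[flip_at, start + duration)`, with the same
#' sensor projection throughout. A classifier trained before the flip tested
#' after it sees the discriminative pattern inverted, producing AUC below
#' chance - the anti-generalization phenomenon.
#'
#' @inheritParams sequential_scenario
#' @param flip_at 0-based sample at which the coupling sign flips; must lie in
#'   `[start, start + duration)`.
#' @param second_amplitude amplitude of the post-flip segment relative to the
#'   first (1 = full reversal; < 1 = attenuated, partial reversal).
#' @export
reversal_scenario <- function(duration = 40L, start = 10L, flip_at = 30L,
                              n_samples = 80L, second_amplitude = 1) {
  if (duration < 1L) stop("duration must be >= 1")
  if (flip_at < start || flip_at >= start + duration)
    stop("flip_at must lie within the active window [start, start + duration)")
  rel <- seq.int(start, start + duration - 1L)
  sgn <- ifelse(rel < flip_at, 1, -second_amplitude)
  gens <- list(list(onset = as.integer(start), duration = as.integer(duration),
                    sign = sgn))
  new_scenario(gens, n_samples, "reversal")
}

#' @export
print.tg_scenario <- function(x, ...) {
  cat(sprintf("<tg_scenario> %s: %d generator(s) over %d samples\n",
              x$kind, length(x$generators), x$n_samples))
  for (g in x$generators)
    cat(sprintf("  window [%d, %d)%s\n", g$onset, g$onset + g$duration,
                if (any(g$sign < 0)) " with sign reversal" else ""))
  invisible(x)
}

#' Simulation configuration
#'
#' Bundles a scenario with the sampling conditions of the simulated study:
#' 50 trials (half per class) over 20 sensors and 80 time samples, a
#' signal-to-noise ratio of 0.5, and a group of 10 subjects. SNR is defined as
#' the root-mean-square of the noiseless signal over informative entries
#' (trials x channels x active samples) divided by the noise standard
#' deviation; `snr = Inf` means noiseless.
#'
#' @param scenario a `tg_scenario`.
#' @param n_trials trials per subject, even (half per class).
#' @param n_channels simulated sensors.
#' @param n_samples time samples per epoch; must match the scenario.
#' @param snr signal-to-noise ratio (> 0, or `Inf`).
#' @param n_subjects subjects per simulated group.
#' @param sample_rate nominal sampling rate (Hz) used to give simulated epochs
#'   a time axis (t = 0 at the first sample).
#' @param seed master seed; per-subject streams are derived from it.
#' @return A `sim_config`.
#' @export
sim_config <- function(scenario, n_trials = 50L, n_channels = 20L,
                       n_samples = 80L, snr = 0.5, n_subjects = 10L,
                       sample_rate = 256, seed = 1L) {
  stopifnot(inherits(scenario, "tg_scenario"))
  n_trials <- as.integer(n_trials)
  if (n_trials < 2L || n_trials %% 2L != 0L)
    stop("n_trials must be even (balanced classes)")
  if (!is.numeric(snr) || snr <= 0) stop("snr must be > 0 (Inf = noiseless)")
  if (as.integer(n_samples) != scenario$n_samples)
    stop(sprintf("scenario is defined over %d samples but n_samples = %d",
                 scenario$n_samples, n_samples))
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  structure(list(scenario = scenario, n_trials = n_trials,
                 n_channels = as.integer(n_channels),
                 n_samples = as.integer(n_samples), snr = snr,
                 n_subjects = as.integer(n_subjects),
                 sample_rate = sample_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# Channels x samples noiseless class-pattern M(c, t) = sum_g A_g(t) s_g(t) C_g(c),
# given per-generator projections (channels x generators matrix).
scenario_pattern <- function(scenario, projections, n_samples) {
  M <- matrix(0, nrow = nrow(projections), ncol = n_samples)
  for (i in seq_along(scenario$generators)) {
    g <- scenario$generators[[i]]
    if (g$duration == 0L) next
    cols <- seq.int(g$onset + 1L, g$onset + g$duration)
    M[, cols] <- M[, cols] + outer(projections[, i], g$sign)
  }
  M
}

#' Simulate one subject's epochs
#'
#' Draws fresh generator projections from N(0, 1), builds the deterministic
#' class-signed signal, and adds i.i.d. Gaussian noise calibrated to the
#' configured SNR. Deterministic given `subject_seed`. The first half of the
#' trials is the standard class (y = -1), the second half the deviant class
#' (y = +1); labels are carried via `local_class` (subclasses LSGS / LDGD as in
#' block type 1 of the local-global design).
#'
#' @param config a [sim_config()].
#' @param subject_seed integer seed for this subject's projections and noise.
#' @param subject_id identifier stored in the returned epochs.
#' @return An [epochs_set()] of dimension
#'   `n_trials x n_channels x n_samples`.
#' @export
simulate_subject <- function(config, subject_seed, subject_id = "sim01") {
  stopifnot(inherits(config, "sim_config"))
  nt <- config$n_trials; nc <- config$n_channels; ns <- config$n_samples
  nG <- length(config$scenario$generators)
  y <- rep(c(-1, 1), each = nt / 2L)
  with_seed(subject_seed, {
    proj <- matrix(rnorm(nc * max(nG, 1L)), nrow = nc)
    M <- scenario_pattern(config$scenario, proj, ns)
    informative <- colSums(abs(M)) > 0
    rms <- if (any(informative)) sqrt(mean(M[, informative]^2)) else 0
    sigma <- if (is.infinite(config$snr)) 0 else if (rms == 0) 1 else
      rms / config$snr
    signal <- outer(y, M)                       # trials x channels x samples
    data <- if (sigma > 0)
      signal + array(rnorm(length(signal), sd = sigma), dim = dim(signal))
    else signal
  })
  labels <- trial_labels(
    local_class = ifelse(y > 0, "deviant", "standard"),
    global_class = ifelse(y > 0, "deviant", "standard"),
    block_id = 1L, block_type = 1L, analyzed = TRUE)
  epochs_set(data, times = (seq_len(ns) - 1L) / config$sample_rate,
             sample_rate = config$sample_rate, labels = labels,
             subject_id = subject_id)
}

#' Simulate a group of subjects
#'
#' Repeats [simulate_subject()] with fresh projections and noise per subject;
#' per-subject seeds are derived deterministically from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A list of `n_subjects` [epochs_set()] objects.
#' @export
simulate_group <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed, config$n_subjects)
  lapply(seq_len(config$n_subjects), function(s)
    simulate_subject(config, seeds[s], subject_id = sprintf("sim%02d", s)))
}
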