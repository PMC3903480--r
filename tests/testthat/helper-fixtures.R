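# Small fixtures built in code, shared across test files.

# A tiny labelled epochs object with deterministic content.
tiny_epochs <- function(n_trials = 4L, n_channels = 2L, n_samples = 3L,
                        sample_rate = 64) {
  lab <- trial_labels(rep(c("standard", "deviant"),
                          length.out = n_trials),
                      rep("standard", n_trials))
  epochs_set(array(as.numeric(seq_len(n_trials * n_channels * n_samples)),
                   c(n_trials, n_channels, n_samples)),
             times = (seq_len(n_samples) - 1L) / sample_rate,
             sample_rate = sample_rate, labels = lab,
             subject_id = "fix", channel_ids = LETTERS[seq_len(n_channels)])
}

# A quick simulated subject for decoding tests.
quick_subject <- function(scenario = sustained_scenario(12, 4, n_samples = 20),
                          n_trials = 20L, n_channels = 6L, snr = 2,
                          seed = 11L) {
  cfg <- sim_config(scenario, n_trials = n_trials, n_channels = n_channels,
                    n_samples = scenario$n_samples, snr = snr,
                    n_subjects = 1L, seed = seed)
  simulate_subject(cfg, seed)
}

# Brute-force AUC oracle: direct count over all positive-negative pairs.
auc_bruteforce <- function(scores, y) {
  p <- scores[y > 0]
  n <- scores[y <= 0]
  tot <- 0
  for (a in p) for (b in n) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(p) * length(n))
}

# A minimal stand-in tgm object for statistics-only tests.
fake_tgm <- function(auc_mat, times = NULL, subject_id = "fake") {
  nT <- nrow(auc_mat)
  if (is.null(times)) times <- (seq_len(nT) - 1L) / 256
  structure(list(auc = auc_mat, train_times = times, test_times = times,
                 probabilities = NULL, y = NULL, subject_id = subject_id,
                 contrast = "local", sample_rate = 256),
            class = "tgm")
}
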