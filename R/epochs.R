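#' Per-trial labels for the local-global oddball design
#'
#' Builds the trial-label table used throughout the package. Each trial of the
#' local-global paradigm is a five-sound sequence that is a *local* standard or
#' deviant (fifth sound identical to, or different from, the first four) and a
#' *global* standard or deviant (frequent or rare sequence within its block).
#' The four subclasses LSGS, LDGS, LSGD, LDGD cross the two factors; habituation
#' run-in trials and trials immediately following a global deviant are flagged
#' `analyzed = FALSE` and excluded from all decoding contrasts.
#'
#' @param local_class character vector, `"standard"` or `"deviant"` per trial.
#' @param global_class character vector, `"standard"` or `"deviant"` per trial.
#' @param block_id integer block index per trial.
#' @param block_type integer, 1 or 2; determines which local class is the
#'   frequent (global standard) one in that block.
#' @param analyzed logical; `FALSE` for habituation trials and trials that
#'   immediately follow a global deviant.
#' @return A `data.frame` with columns `local_class`, `global_class`,
#'   `subclass`, `block_id`, `block_type`, `analyzed`.
#' @export
trial_labels <- function(local_class, global_class, block_id = 1L,
                         block_type = 1L, analyzed = TRUE) {
  n <- length(local_class)
  if (length(global_class) != n)
    stop("local_class and global_class must have the same length")
  ok <- c("standard", "deviant")
  if (!all(local_class %in% ok) || !all(global_class %in% ok))
    stop('classes must be "standard" or "deviant"')
  block_id <- rep_len(as.integer(block_id), n)
  block_type <- rep_len(as.integer(block_type), n)
  analyzed <- rep_len(as.logical(analyzed), n)
  if (!all(block_type %in% c(1L, 2L)))
    stop("block_type must be 1 or 2")
  subclass <- paste0(ifelse(local_class == "standard", "LS", "LD"),
                     ifelse(global_class == "standard", "GS", "GD"))
  data.frame(local_class = local_class, global_class = global_class,
             subclass = subclass, block_id = block_id,
             block_type = block_type, analyzed = analyzed,
             stringsAsFactors = FALSE)
}

#' Epoched multichannel recordings
#'
#' Container for epoched data: a trials x channels x time-samples array with an
#' evenly spaced time axis (seconds, 0 = onset of the critical fifth sound) and
#' one [trial_labels()] row per trial.
#'
#' @param data numeric 3-D array, `trials x channels x samples`, no missing
#'   values.
#' @param times numeric vector of time points in seconds, evenly spaced at
#'   `1/sample_rate`.
#' @param sample_rate sampling rate in Hz.
#' @param labels `data.frame` from [trial_labels()], one row per trial.
#' @param subject_id character scalar.
#' @param channel_ids character vector of channel names; defaults to
#'   `MEG001...`.
#' @return An object of class `epochs_set`.
#' @export
epochs_set <- function(data, times, sample_rate, labels,
                       subject_id = "S01", channel_ids = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (trials x channels x samples)")
  d <- dim(data)
  if (anyNA(data)) stop("`data` contains missing values")
  if (length(times) != d[3L])
    stop(sprintf("length(times) [%d] does not match n_samples [%d]",
                 length(times), d[3L]))
  stop_if_not_scalar_number(sample_rate, "sample_rate")
  dt <- 1 / sample_rate
  if (d[3L] > 1L && max(abs(diff(times) - dt)) > dt * 1e-4)
    stop("`times` must be evenly spaced at 1/sample_rate")
  if (!is.data.frame(labels) || nrow(labels) != d[1L])
    stop(sprintf("label/trial count mismatch: %d labels for %d trials",
                 if (is.data.frame(labels)) nrow(labels) else length(labels),
                 d[1L]))
  need <- c("local_class", "global_class", "subclass", "block_id",
            "block_type", "analyzed")
  miss <- setdiff(need, names(labels))
  if (length(miss))
    stop("labels missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(channel_ids))
    channel_ids <- sprintf("MEG%03d", seq_len(d[2L]))
  if (length(channel_ids) != d[2L])
    stop("channel_ids length does not match n_channels")
  structure(list(data = data, times = as.numeric(times),
                 sample_rate = as.numeric(sample_rate),
                 labels = labels, subject_id = as.character(subject_id),
                 channel_ids = as.character(channel_ids)),
            class = "epochs_set")
}

#' @export
print.epochs_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epochs_set> subject %s: %d trials x %d channels x %d samples\n",
              x$subject_id, d[1L], d[2L], d[3L]))
  cat(sprintf("  time %.3f .. %.3f s @ %g Hz; %d analyzed trials\n",
              x$times[1L], x$times[length(x$times)], x$sample_rate,
              sum(x$labels$analyzed)))
  tab <- table(x$labels$subclass[x$labels$analyzed])
  if (length(tab))
    cat("  analyzed subclasses:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.epochs_set <- function(x) dim(x$data)

#' Baseline-correct epoched data
#'
#' Subtracts, for every trial and channel, the mean amplitude over a baseline
#' window from the whole epoch. The default window is the 200 ms preceding the
#' onset of the first of the five sounds (sounds at 150 ms stimulus-onset
#' asynchrony, so the first sound starts 600 ms before the critical fifth one).
#'
#' @param epochs an [epochs_set()].
#' @param window numeric length-2, half-open baseline interval
#'   `[t_start, t_end)` in seconds.
#' @return A baseline-corrected `epochs_set`. The operation is idempotent and
#'   linear in the data.
#' @export
baseline_correct <- function(epochs, window = c(-0.8, -0.6)) {
  stopifnot(inherits(epochs, "epochs_set"))
  if (length(window) != 2L || !is.numeric(window) || window[1L] >= window[2L])
    stop("`window` must be (t_start, t_end) with t_start < t_end")
  times <- epochs$times
  dt <- 1 / epochs$sample_rate
  tol <- dt * 1e-6
  if (window[1L] < times[1L] - tol || window[2L] > times[length(times)] + dt + tol)
    stop(sprintf("baseline window [%g, %g) outside recorded range [%g, %g]",
                 window[1L], window[2L], times[1L], times[length(times)]))
  sel <- times >= window[1L] - tol & times < window[2L] - tol
  if (!any(sel)) stop("baseline window contains no samples")
  d <- dim(epochs$data)
  base <- epochs$data[, , sel, drop = FALSE]
  m <- rowMeans(matrix(base, nrow = d[1L] * d[2L]))   # per trial x channel
  epochs$data <- epochs$data - array(m, dim = d)
  epochs
}

#' Extract a decoding contrast from labelled epochs
#'
#' Selects the analyzed trials and assigns the classification target
#' `y = -1` (standard) / `+1` (deviant) from the local or the global class.
#' Both contrasts select the identical trial set (all analyzed trials) and
#' differ only in the class assignment, so both are balanced across blocks by
#' construction. The subclass of every trial is retained for stratification and
#' sample weighting.
#'
#' @param epochs an [epochs_set()].
#' @param name `"local"` or `"global"`.
#' @return An object of class `contrast_spec` with elements `name`, `trials`
#'   (indices into the epochs), `y`, and `subclass`.
#' @export
make_contrast <- function(epochs, name = c("local", "global")) {
  stopifnot(inherits(epochs, "epochs_set"))
  name <- match.arg(name)
  lab <- epochs$labels
  keep <- which(lab$analyzed)
  if (!length(keep)) stop("no analyzed trials")
  cls <- if (name == "local") lab$local_class[keep] else lab$global_class[keep]
  y <- ifelse(cls == "deviant", 1, -1)
  if (!any(y > 0) || !any(y < 0))
    stop(sprintf("contrast '%s' has a class with zero analyzed trials", name))
  structure(list(name = name, trials = keep, y = y,
                 subclass = factor(lab$subclass[keep]),
                 n_deviant = sum(y > 0), n_standard = sum(y < 0)),
            class = "contrast_spec")
}

#' @export
print.contrast_spec <- function(x, ...) {
  cat(sprintf("<contrast_spec> %s: %d deviant vs %d standard trials\n",
              x$name, x$n_deviant, x$n_standard))
  invisible(x)
}
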