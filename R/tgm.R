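# Temporal generalization: fit one classifier per training time under
# stratified cross-validation and test it at every other time sample. Per-trial
# probabilities are pooled across folds (each trial is predicted exactly once
# per train-time x test-time cell, by the model from the fold in which it was
# held out), then one AUC is computed per cell. CV hygiene: trials in a
# training set at time t never enter the generalization at any t'.

# Shared engine for the full matrix and the standalone diagonal curve. Both
# paths use the identical per-fold fit and the identical prediction
# arithmetic, so the diagonal of the matrix and the diagonal-decoding curve
# agree bit-for-bit under shared folds.
tg_engine <- function(X, y, folds, C, weights, diagonal_only = FALSE) {
  d <- dim(X)
  nt <- d[1L]; nc <- d[2L]; nT <- d[3L]
  prob <- if (diagonal_only) matrix(NA_real_, nt, nT) else
    array(NA_real_, c(nt, nT, nT))
  coefs <- matrix(0, nc, nT)
  for (f in seq_len(folds$k)) {
    te <- folds$fold == f
    if (!any(te)) next
    tr <- !te
    Xte <- matrix(aperm(X[te, , , drop = FALSE], c(1L, 3L, 2L)), ncol = nc)
    wtr <- weights[tr]
    for (t in seq_len(nT)) {
      m <- train_timepoint(X[tr, , t], y[tr], weights = wtr, C = C)
      # fold the z-scoring into the linear form so one product scores all t'
      weff <- m$w / m$normalization$sd
      beff <- m$b - sum(m$normalization$mean * weff)
      p <- platt_predict(m$calibration, drop(Xte %*% weff) + beff)
      pm <- matrix(p, ncol = nT)
      if (diagonal_only) prob[te, t] <- pm[, t] else prob[te, t, ] <- pm
      coefs[, t] <- coefs[, t] + weff
    }
  }
  list(prob = prob, coef = coefs / folds$k)
}

auc_by_column <- function(P, pos) {
  # AUC of each column of P against the fixed positive-class indicator
  n1 <- sum(pos)
  n2 <- length(pos) - n1
  R <- apply(P, 2L, rank)
  (colSums(R[pos, , drop = FALSE]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Build a temporal generalization matrix
#'
#' For every fold and training time `t`, a [train_timepoint()] model is fitted
#' on the training trials at `t` and applied to the held-out trials at every
#' test time `t'`; pooled per-trial probabilities give one AUC per
#' (train time, test time) cell.
#'
#' @param epochs an [epochs_set()].
#' @param contrast a [make_contrast()] object for these epochs.
#' @param folds a [stratified_folds()] assignment for the contrast.
#' @param C regularization constant (default 1).
#' @param weights per-trial loss weights; defaults to [subclass_weights()].
#' @param store_probabilities keep the trials x train x test probability array
#'   in the result (needed for within-subject statistics and CSV export).
#' @return An object of class `tgm`; see [tgm()] for the fields.
#' @export
run_tgm <- function(epochs, contrast, folds, C = 1, weights = NULL,
                    store_probabilities = TRUE) {
  stopifnot(inherits(epochs, "epochs_set"), inherits(contrast, "contrast_spec"),
            inherits(folds, "fold_assignment"))
  if (length(folds$fold) != length(contrast$y))
    stop("fold assignment does not match the contrast's trial count")
  if (is.null(weights)) weights <- subclass_weights(contrast)
  X <- epochs$data[contrast$trials, , , drop = FALSE]
  eng <- tg_engine(X, contrast$y, folds, C, weights)
  nT <- dim(X)[3L]
  pos <- contrast$y > 0
  auc_mat <- matrix(NA_real_, nT, nT)
  for (t in seq_len(nT))
    auc_mat[t, ] <- auc_by_column(eng$prob[, t, ], pos)
  structure(list(auc = auc_mat,
                 train_times = epochs$times, test_times = epochs$times,
                 probabilities = if (store_probabilities) eng$prob else NULL,
                 y = contrast$y, subclass = contrast$subclass,
                 trials = contrast$trials, folds = folds,
                 contrast = contrast$name, C = C,
                 coef = eng$coef,
                 subject_id = epochs$subject_id,
                 channel_ids = epochs$channel_ids,
                 sample_rate = epochs$sample_rate),
            class = "tgm")
}

#' Diagonal (train = test time) decoding curve
#'
#' Computes the time course of decoding performance with a classifier trained
#' and tested at the same sample, using the same folds, models and prediction
#' arithmetic as [run_tgm()]; with shared folds its AUC curve equals the
#' diagonal of the full matrix exactly.
#'
#' @inheritParams run_tgm
#' @return List with `auc` (per time sample), `times`, and the pooled
#'   per-trial `probabilities` (trials x times).
#' @export
decode_diagonal <- function(epochs, contrast, folds, C = 1, weights = NULL) {
  stopifnot(inherits(epochs, "epochs_set"), inherits(contrast, "contrast_spec"),
            inherits(folds, "fold_assignment"))
  if (is.null(weights)) weights <- subclass_weights(contrast)
  X <- epochs$data[contrast$trials, , , drop = FALSE]
  eng <- tg_engine(X, contrast$y, folds, C, weights, diagonal_only = TRUE)
  list(auc = auc_by_column(eng$prob, contrast$y > 0),
       times = epochs$times, probabilities = eng$prob)
}

#' Temporal generalization decoding of one subject
#'
#' The main fitting function. Extracts the requested contrast, builds
#' stratified folds, and runs the full train-time x test-time decoding
#' analysis: per-channel z-scoring inside each fold, a linear SVM (hinge loss,
#' `C = 1`) with subclass sample weights at each training time, Platt-calibrated
#' probabilities pooled over held-out folds, and one ROC AUC per cell.
#'
#' @param epochs an [epochs_set()].
#' @param contrast `"local"`, `"global"`, or a [make_contrast()] object.
#' @param k number of stratified cross-validation folds (default 10).
#' @param seed RNG seed for the fold shuffle.
#' @param C regularization constant of the linear SVM.
#' @param store_probabilities keep per-trial probabilities (needed for
#'   within-subject statistics).
#' @return An object of class `tgm` with fields `auc` (train x test matrix of
#'   AUC), `train_times`/`test_times` (seconds), `probabilities`
#'   (trials x train x test, or `NULL`), `y`, `subclass`, `folds`, `coef`
#'   (channels x train-times fold-averaged discriminant weights), `contrast`,
#'   `subject_id`, `sample_rate`.
#' @seealso [tgm_group_stats()] for group inference, [plot.tgm()] for the
#'   heatmap, [tgm_diagonal()] for the diagonal curve.
#' @examples
#' cfg <- sim_config(sustained_scenario(12, 4, n_samples = 20),
#'                   n_trials = 20, n_channels = 5, n_samples = 20,
#'                   snr = 1, n_subjects = 1, seed = 7)
#' ep <- simulate_subject(cfg, 7)
#' fit <- tgm(ep, "local", k = 5, seed = 1)
#' fit
#' @export
tgm <- function(epochs, contrast = c("local", "global"), k = 10L, seed = 1L,
                C = 1, store_probabilities = TRUE) {
  if (is.character(contrast)) {
    contrast <- match.arg(contrast)
    contrast <- make_contrast(epochs, contrast)
  }
  folds <- stratified_folds(contrast, k = k, seed = seed)
  out <- run_tgm(epochs, contrast, folds, C = C,
                 store_probabilities = store_probabilities)
  out$k <- folds$k
  out$seed <- as.integer(seed)
  out
}

#' Extract the diagonal of a temporal generalization matrix
#'
#' @param x a `tgm` object.
#' @return Numeric vector: `auc[i, i]` over training times.
#' @export
tgm_diagonal <- function(x) {
  stopifnot(inherits(x, "tgm"))
  diag(x$auc)
}

#' @export
print.tgm <- function(x, ...) {
  nT <- length(x$train_times)
  dg <- tgm_diagonal(x)
  pk <- which.max(dg)
  cat(sprintf("<tgm> %s contrast, subject %s: %d x %d matrix, %d trials\n",
              x$contrast, x$subject_id, nT, nT, length(x$y)))
  cat(sprintf("  peak diagonal AUC %.3f at %.0f ms\n",
              dg[pk], 1000 * x$train_times[pk]))
  invisible(x)
}

#' @export
summary.tgm <- function(object, ...) {
  dg <- tgm_diagonal(object)
  off <- object$auc
  diag(off) <- NA
  pk <- which.max(dg)
  structure(list(contrast = object$contrast, subject_id = object$subject_id,
                 n_times = length(object$train_times),
                 n_trials = length(object$y),
                 peak_auc = dg[pk], peak_time = object$train_times[pk],
                 mean_diagonal = mean(dg),
                 mean_offdiagonal = mean(off, na.rm = TRUE),
                 diagonal = dg, times = object$train_times),
            class = "summary.tgm")
}

#' @export
print.summary.tgm <- function(x, ...) {
  cat(sprintf("Temporal generalization, %s contrast (subject %s)\n",
              x$contrast, x$subject_id))
  cat(sprintf("  %d trials, %d x %d cells\n", x$n_trials, x$n_times, x$n_times))
  cat(sprintf("  peak diagonal AUC: %.3f at %.0f ms\n",
              x$peak_auc, 1000 * x$peak_time))
  cat(sprintf("  mean diagonal AUC: %.3f; mean off-diagonal AUC: %.3f\n",
              x$mean_diagonal, x$mean_offdiagonal))
  invisible(x)
}

#' @export
coef.tgm <- function(object, ...) {
  cf <- object$coef
  dimnames(cf) <- list(object$channel_ids,
                       sprintf("%.0fms", 1000 * object$train_times))
  cf
}

diverging_palette <- function(n = 64L) {
  grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(n)
}

#' Heatmap of a temporal generalization matrix
#'
#' Test time runs along the horizontal axis, train time along the vertical
#' axis, with a diverging color scale centered on chance (AUC 0.5).
#'
#' @param x a `tgm` object.
#' @param zlim color limits; defaults to symmetric around 0.5.
#' @param ... passed to [graphics::image()].
#' @export
plot.tgm <- function(x, zlim = NULL, ...) {
  if (is.null(zlim)) {
    half <- max(abs(x$auc - 0.5), 0.05)
    zlim <- c(0.5 - half, 0.5 + half)
  }
  graphics::image(x$test_times, x$train_times, t(x$auc),
                  col = diverging_palette(), zlim = zlim,
                  xlab = "test time (s)", ylab = "train time (s)",
                  main = sprintf("TGM, %s contrast (%s)", x$contrast,
                                 x$subject_id), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Export per-cell AUC values as CSV
#'
#' @param x a `tgm` object.
#' @param path output path.
#' @param stats optional [tgm_group_stats()] / [within_subject_map()] result
#'   on the same grid; adds `p` and `significant` columns.
#' @export
export_tgm_csv <- function(x, path, stats = NULL) {
  stopifnot(inherits(x, "tgm"))
  grid <- expand.grid(train_time = x$train_times, test_time = x$test_times)
  out <- data.frame(grid, auc = as.vector(x$auc))
  if (!is.null(stats)) {
    out$p <- as.vector(stats$p)
    out$significant <- as.vector(stats$mask)
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export pooled per-trial predictions as CSV
#'
#' One row per (trial, train time, test time): the Platt probability of the
#' deviant class from the fold in which the trial was held out, the true
#' class, and the fold index.
#'
#' @param x a `tgm` object fitted with `store_probabilities = TRUE`.
#' @param path output path.
#' @export
export_predictions_csv <- function(x, path) {
  stopifnot(inherits(x, "tgm"))
  if (is.null(x$probabilities))
    stop("tgm was fitted with store_probabilities = FALSE")
  d <- dim(x$probabilities)
  grid <- expand.grid(trial = x$trials,
                      train_time = x$train_times,
                      test_time = x$test_times)
  out <- data.frame(grid, probability = as.vector(x$probabilities),
                    y = rep(x$y, d[2L] * d[3L]),
                    fold = rep(x$folds$fold, d[2L] * d[3L]))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
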