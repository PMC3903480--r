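# Per-timepoint classifier: per-channel z-scoring (training statistics only),
# weighted linear C-SVC (compiled SMO solver), and Platt sigmoid calibration
# from decision values to deviant probabilities.

#' Fit a per-channel normalizer on training data
#'
#' Estimates per-channel mean and standard deviation from training trials
#' only. A channel that is constant in the training data gets SD 1 so it maps
#' to all-zeros instead of dividing by zero.
#'
#' @param train_data numeric matrix, trials x channels, at one time sample.
#' @return A `tg_normalizer` with `mean` and `sd` per channel.
#' @export
fit_normalizer <- function(train_data) {
  train_data <- as.matrix(train_data)
  if (nrow(train_data) < 2L) stop("need at least 2 training trials")
  m <- colMeans(train_data)
  s <- apply(train_data, 2L, sd)
  s[s == 0] <- 1
  structure(list(mean = m, sd = s), class = "tg_normalizer")
}

#' Apply a fitted normalizer
#'
#' @param normalizer a [fit_normalizer()] object.
#' @param data trials x channels matrix.
#' @return The z-scored matrix, using the training statistics.
#' @export
apply_normalizer <- function(normalizer, data) {
  stopifnot(inherits(normalizer, "tg_normalizer"))
  data <- as.matrix(data)
  if (ncol(data) != length(normalizer$mean))
    stop("channel count mismatch between data and normalizer")
  sweep(sweep(data, 2L, normalizer$mean, "-"), 2L, normalizer$sd, "/")
}

# Platt sigmoid P(deviant | f) = 1 / (1 + exp(A f + B)), coefficients fitted
# by regularized maximum likelihood on the training decision values with the
# usual shifted targets (N+ + 1)/(N+ + 2) and 1/(N- + 2), Newton iterations
# with backtracking line search.
platt_fit <- function(decision, y, max_iter = 100L, min_step = 1e-10,
                      sigma = 1e-12) {
  pos <- y > 0
  prior1 <- sum(pos)
  prior0 <- length(y) - prior1
  hi <- (prior1 + 1) / (prior1 + 2)
  lo <- 1 / (prior0 + 2)
  t <- ifelse(pos, hi, lo)

  objective <- function(A, B) {
    fApB <- decision * A + B
    sum(ifelse(fApB >= 0,
               t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }

  A <- 0
  B <- log((prior0 + 1) / (prior1 + 1))
  fval <- objective(A, B)
  for (it in seq_len(max_iter)) {
    fApB <- decision * A + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
    d2 <- p * (1 - p)
    h11 <- sigma + sum(decision * decision * d2)
    h22 <- sigma + sum(d2)
    h21 <- sum(decision * d2)
    d1 <- t - p
    g1 <- sum(decision * d1)
    g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    stepsize <- 1
    repeat {
      if (stepsize < min_step) break
      newA <- A + stepsize * dA
      newB <- B + stepsize * dB
      newf <- objective(newA, newB)
      if (newf < fval + 1e-4 * stepsize * gd) {
        A <- newA; B <- newB; fval <- newf
        break
      }
      stepsize <- stepsize / 2
    }
    if (stepsize < min_step) break
  }
  c(A = A, B = B)
}

platt_predict <- function(calibration, decision) {
  fApB <- decision * calibration[["A"]] + calibration[["B"]]
  ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
}

#' Train one time-sample classifier
#'
#' Fits the full per-timepoint decoding model at a single time sample:
#' per-channel z-scoring (training trials only), a linear maximum-margin
#' classifier with hinge loss, regularization constant `C` fixed at 1 and
#' per-trial sample weights in the loss, and a Platt sigmoid mapping decision
#' values to the probability of the deviant class, fitted on the training
#' outputs.
#'
#' @param train_data trials x channels matrix at one time sample (raw,
#'   unnormalized).
#' @param y class labels, `-1` (standard) / `+1` (deviant); both classes must
#'   be present.
#' @param weights per-trial weights (default all 1); see [subclass_weights()].
#' @param time training time in seconds (metadata only).
#' @param C regularization constant (default 1).
#' @return A `timepoint_model` with elements `w`, `b`, `normalization`,
#'   `calibration`, `C`, `train_time`.
#' @export
train_timepoint <- function(train_data, y, weights = NULL, time = NA_real_,
                            C = 1) {
  train_data <- as.matrix(train_data)
  y <- as.numeric(y)
  if (!any(y > 0) || !any(y < 0))
    stop("training set contains a single class")
  if (is.null(weights)) weights <- rep(1, length(y))
  if (length(weights) != length(y) || any(weights <= 0))
    stop("weights must be positive, one per trial")
  norm <- fit_normalizer(train_data)
  Z <- apply_normalizer(norm, train_data)
  fit <- .svm_linear_fit_cpp(Z, ifelse(y > 0, 1, -1), C * weights)
  decision <- drop(Z %*% fit$w) + fit$b
  structure(list(w = fit$w, b = fit$b, normalization = norm,
                 calibration = platt_fit(decision, y), C = C,
                 train_time = time, n_channels = ncol(train_data),
                 alpha = fit$alpha),
            class = "timepoint_model")
}

#' Decision values of a timepoint model
#'
#' @param model a [train_timepoint()] model.
#' @param data trials x channels matrix (raw; the model's normalization is
#'   applied internally).
#' @return Numeric vector of signed decision values (positive = deviant side).
#' @export
decision_values <- function(model, data) {
  stopifnot(inherits(model, "timepoint_model"))
  data <- as.matrix(data)
  if (ncol(data) != model$n_channels)
    stop(sprintf("data has %d channels but the model expects %d",
                 ncol(data), model$n_channels))
  drop(apply_normalizer(model$normalization, data) %*% model$w) + model$b
}

#' Calibrated probability of the deviant class
#'
#' Applies the model's normalization, linear decision function and Platt
#' sigmoid. Probabilities lie in (0, 1) and are monotone in the decision
#' value.
#'
#' @inheritParams decision_values
#' @return Numeric vector of probabilities.
#' @export
predict_probability <- function(model, data) {
  platt_predict(model$calibration, decision_values(model, data))
}
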