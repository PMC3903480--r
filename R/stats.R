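# Nonparametric inference on decoding outputs: Mann-Whitney within subject
# (trials as the random variable), Wilcoxon signed-rank across subjects, and
# Benjamini-Hochberg FDR over train x test cells. All tests are two-sided by
# default because below-chance (sign-reversed) generalization is meaningful.

#' Within-subject test of decoding (Mann-Whitney U)
#'
#' Tests whether the classifier's continuous outputs separate the two classes,
#' with trials as the random variable. The U statistic shares the tie
#' convention of [auc()], so `U = auc(scores, y) * n1 * n2` exactly. The exact
#' null distribution is used when both groups are small and the scores are
#' untied; otherwise the normal approximation with tie and continuity
#' correction (the [stats::wilcox.test()] conventions).
#'
#' @param scores per-trial continuous classifier outputs.
#' @param y per-trial class; positive = deviant.
#' @param exact force (`TRUE`/`FALSE`) or auto-select (`NULL`) the exact test.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return An object of class `htest` with the U statistic; the `estimate`
#'   field carries the AUC effect size.
#' @export
within_subject_test <- function(scores, y, exact = NULL,
                                alternative = "two.sided") {
  pos <- y > 0
  if (!any(pos) || !any(!pos)) stop("both classes must be present")
  n1 <- sum(pos); n2 <- sum(!pos)
  if (length(unique(scores)) == 1L) {
    # fully tied scores: U sits exactly at its null center, no evidence
    out <- list(statistic = c(U = n1 * n2 / 2), p.value = 1,
                estimate = c(AUC = 0.5),
                method = "Mann-Whitney U test on classifier outputs",
                alternative = alternative,
                data.name = sprintf("%d deviant vs %d standard trials",
                                    n1, n2),
                n = c(n1 = n1, n2 = n2))
    class(out) <- "htest"
    return(out)
  }
  ht <- suppressWarnings(stats::wilcox.test(
    scores[pos], scores[!pos], exact = exact, correct = TRUE,
    alternative = alternative))
  names(ht$statistic) <- "U"
  ht$estimate <- c(AUC = unname(ht$statistic) / (n1 * n2))
  ht$method <- "Mann-Whitney U test on classifier outputs"
  ht$data.name <- sprintf("%d deviant vs %d standard trials", n1, n2)
  ht$n <- c(n1 = n1, n2 = n2)
  ht
}

# Exact tail probabilities of the signed-rank statistic W under random sign
# flips, conditional on the observed midranks. Midranks are doubled so the
# convolution runs on integers; the distribution of 2W is built by dynamic
# programming over subjects (counts of sign patterns reaching each value).
signrank_exact_tails <- function(r, V) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  counts <- numeric(total + 1L)   # index w + 1 holds #patterns with 2W = w
  counts[1L] <- 1
  for (ri in r2) {
    shifted <- c(rep(0, ri), counts[seq_len(total + 1L - ri)])
    counts <- counts + shifted
  }
  counts <- counts / 2^length(r2)
  v2 <- as.integer(round(2 * V))
  c(less = sum(counts[seq_len(v2 + 1L)]),
    greater = sum(counts[seq.int(v2 + 1L, total + 1L)]))
}

# Vectorized two-sided Mann-Whitney normal approximation (tie + continuity
# corrected), one p per column of the score matrix. Matches
# wilcox.test(exact = FALSE, correct = TRUE) and is used for per-cell maps.
mw_p_columns <- function(P, pos) {
  n1 <- sum(pos)
  n2 <- length(pos) - n1
  n <- n1 + n2
  mu <- n1 * n2 / 2
  vapply(seq_len(ncol(P)), function(j) {
    s <- P[, j]
    r <- rank(s)
    U <- sum(r[pos]) - n1 * (n1 + 1) / 2
    nt <- table(s)
    tie <- sum(nt^3 - nt)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- U - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    min(1, 2 * pnorm(-abs(z)))
  }, numeric(1))
}

#' Across-subject test (Wilcoxon signed rank)
#'
#' Tests per-subject values (e.g. one AUC per subject at a cell) against a
#' null value, or paired per-subject differences against zero. The exact null
#' distribution is used for n <= 25 when there are no zeros or ties in the
#' absolute differences; otherwise the tie- and continuity-corrected normal
#' approximation.
#'
#' @param per_subject_values numeric vector, one value per subject.
#' @param null_value the null location (0.5 for AUC against chance; 0 for
#'   paired differences).
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return An `htest` with statistic `V` (sum of positive ranks), p-value,
#'   `n` (non-zero differences) and `direction` (+1 above the null, -1 below).
#' @export
across_subject_test <- function(per_subject_values, null_value = 0.5,
                                alternative = "two.sided") {
  x <- as.numeric(per_subject_values)
  if (length(x) < 2L) stop("need at least 2 subjects")
  d <- x - null_value
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; p = 1")
    out <- list(statistic = c(V = 0), p.value = 1, n = 0L, direction = 0,
                method = "Wilcoxon signed rank test", alternative = alternative,
                data.name = deparse(substitute(per_subject_values)))
    class(out) <- "htest"
    return(out)
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 25L) {
    # exact sign-flip null of W conditional on the observed (mid)ranks;
    # handles ties, and reduces to the psignrank distribution without them
    tails <- signrank_exact_tails(r, V)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(tails["less"], tails["greater"])),
                greater = unname(tails["greater"]),
                less = unname(tails["less"]))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    nt <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(nt^3 - nt) / 48
    z <- V - mu
    zc <- switch(alternative,
                 two.sided = sign(z) * 0.5,
                 greater = 0.5, less = -0.5)
    z <- (z - zc) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = min(1, 2 * pnorm(-abs(z))),
                greater = pnorm(z, lower.tail = FALSE),
                less = pnorm(z))
    exact <- FALSE
  }
  out <- list(statistic = c(V = V), p.value = p, n = n,
              direction = sign(V - n * (n + 1) / 4),
              method = paste0("Wilcoxon signed rank test",
                              if (exact) " (exact)" else
                                " (normal approximation)"),
              alternative = alternative, null.value = c(location = null_value),
              data.name = deparse(substitute(per_subject_values)))
  class(out) <- "htest"
  out
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up procedure: with ordered p-values `p_(1) <= ... <= p_(m)`, reject
#' all `p <= p_(k)` where `k = max{ i : p_(i) <= i q / m }`.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param q FDR level.
#' @return List with `mask` (logical, `TRUE` = rejected), `threshold` (the
#'   data-dependent rejection threshold `p_(k)`, or `NA` if nothing is
#'   rejected), and the BH-`adjusted` p-values.
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  if (!length(p_values))
    return(list(mask = logical(0), threshold = NA_real_,
                adjusted = numeric(0), q = q))
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p_values must lie in (0, 1]")
  adjusted <- p.adjust(p_values, method = "BH")
  mask <- adjusted <= q
  threshold <- if (any(mask)) max(p_values[mask]) else NA_real_
  list(mask = mask, threshold = threshold, adjusted = adjusted, q = q)
}

new_tgm_stats <- function(p, mask, threshold, mean_auc, sem_auc, q,
                          n_subjects, train_times, test_times, level) {
  structure(list(p = p, mask = mask, threshold = threshold,
                 mean_auc = mean_auc, sem_auc = sem_auc, q = q,
                 n_subjects = n_subjects, train_times = train_times,
                 test_times = test_times, level = level),
            class = "tgm_stats")
}

#' Group-level statistics over a stack of TGMs
#'
#' For every train x test cell, tests the per-subject AUCs against chance with
#' the two-sided Wilcoxon signed-rank test, then controls the FDR over all
#' cells (one family) with Benjamini-Hochberg. Also returns the group mean and
#' SEM of the AUC per cell.
#'
#' @param tgms list of [tgm()] objects on a common time grid (one per
#'   subject).
#' @param q FDR level (default 0.05).
#' @param null_value chance level (default 0.5).
#' @return A `tgm_stats` object: matrices `p`, `mask`, `mean_auc`, `sem_auc`,
#'   plus the FDR `threshold`.
#' @export
tgm_group_stats <- function(tgms, q = 0.05, null_value = 0.5) {
  stopifnot(length(tgms) >= 2L, all(vapply(tgms, inherits, TRUE, "tgm")))
  tt <- tgms[[1L]]$train_times
  nT <- length(tt)
  S <- length(tgms)
  stack <- vapply(tgms, function(x) x$auc, matrix(0, nT, nT))   # nT x nT x S
  flat <- matrix(stack, nrow = nT * nT)                         # cells x S
  p <- vapply(seq_len(nrow(flat)), function(i)
    across_subject_test(flat[i, ], null_value = null_value)$p.value,
    numeric(1))
  fdr <- fdr_correct(p, q)
  mean_auc <- matrix(rowMeans(flat), nT, nT)
  sem_auc <- matrix(apply(flat, 1L, sd) / sqrt(S), nT, nT)
  new_tgm_stats(matrix(p, nT, nT), matrix(fdr$mask, nT, nT), fdr$threshold,
                mean_auc, sem_auc, q, S, tt, tgms[[1L]]$test_times, "group")
}

#' Within-subject significance map of one TGM
#'
#' Mann-Whitney test of the pooled per-trial probabilities against the true
#' classes at every cell (trials as the random variable), FDR-corrected over
#' all cells of the subject's matrix as one family.
#'
#' @param x a [tgm()] fitted with `store_probabilities = TRUE`.
#' @param q FDR level.
#' @return A `tgm_stats` object (`n_subjects = 1`).
#' @export
within_subject_map <- function(x, q = 0.05) {
  stopifnot(inherits(x, "tgm"))
  if (is.null(x$probabilities))
    stop("tgm was fitted with store_probabilities = FALSE")
  d <- dim(x$probabilities)
  nT <- d[2L]
  P <- matrix(x$probabilities, nrow = d[1L])   # trials x (train*test)
  p <- mw_p_columns(P, x$y > 0)
  fdr <- fdr_correct(p, q)
  new_tgm_stats(matrix(p, nT, nT), matrix(fdr$mask, nT, nT), fdr$threshold,
                x$auc, matrix(NA_real_, nT, nT), q, 1L,
                x$train_times, x$test_times, "within-subject")
}

#' @export
print.tgm_stats <- function(x, ...) {
  cat(sprintf("<tgm_stats> %s level, %d subject(s), %d x %d cells\n",
              x$level, x$n_subjects, nrow(x$p), ncol(x$p)))
  cat(sprintf("  FDR q = %g: %d significant cells (%.1f%%), threshold %s\n",
              x$q, sum(x$mask), 100 * mean(x$mask),
              if (is.na(x$threshold)) "none" else
                format(x$threshold, digits = 3)))
  below <- sum(x$mask & x$mean_auc < 0.5)
  if (below > 0)
    cat(sprintf("  %d significant cells below chance (AUC < 0.5)\n", below))
  invisible(x)
}

#' @export
plot.tgm_stats <- function(x, what = c("mean", "mask"), ...) {
  what <- match.arg(what)
  if (what == "mean") {
    half <- max(abs(x$mean_auc - 0.5), 0.05)
    graphics::image(x$test_times, x$train_times, t(x$mean_auc),
                    col = diverging_palette(),
                    zlim = c(0.5 - half, 0.5 + half),
                    xlab = "test time (s)", ylab = "train time (s)",
                    main = "group mean AUC", ...)
  } else {
    graphics::image(x$test_times, x$train_times, t(x$mask * 1),
                    col = c("#F7F7F7", "#B2182B"),
                    xlab = "test time (s)", ylab = "train time (s)",
                    main = sprintf("FDR mask (q = %g)", x$q), ...)
  }
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Export a statistics map as CSV
#'
#' @param x a `tgm_stats` object.
#' @param path output path.
#' @export
export_stats_csv <- function(x, path) {
  stopifnot(inherits(x, "tgm_stats"))
  grid <- expand.grid(train_time = x$train_times, test_time = x$test_times)
  write.csv(data.frame(grid, mean_auc = as.vector(x$mean_auc),
                       p = as.vector(x$p), significant = as.vector(x$mask)),
            path, row.names = FALSE)
  invisible(path)
}

#' Generalization duration from significance masks
#'
#' For every training time inside the analysis window, counts the test
#' samples (inside the window) at which the classifier decodes significantly
#' and converts the count to milliseconds. The summary `mean_ms` averages
#' over training times whose *diagonal* cell is significant, the rule used to
#' avoid counting classifiers that never decode at all. The window defaults to
#' the span of diagonal-significant times (data-driven); a fixed window such
#' as the 82-450 ms used for real recordings can be supplied instead.
#'
#' @param mask a logical train x test matrix (e.g. from [tgm_group_stats()]),
#'   or a list of per-subject masks, in which case per-subject durations are
#'   computed and then averaged.
#' @param times the time grid (seconds).
#' @param sample_rate sampling rate in Hz (duration per sample =
#'   `1000 / sample_rate` ms).
#' @param window optional fixed `(t_start, t_end)` window in seconds.
#' @return A `tg_duration` list: `per_train_ms` (matrix subjects x times; `NA`
#'   outside the window), `per_subject_mean_ms`, and the grand `mean_ms`.
#' @export
generalization_duration <- function(mask, times, sample_rate, window = NULL) {
  masks <- if (is.list(mask)) mask else list(mask)
  if (!is.null(window)) {
    if (length(window) != 2L || window[1L] >= window[2L])
      stop("`window` must be (t_start, t_end) with t_start < t_end")
    if (!any(times >= window[1L] & times <= window[2L]))
      stop("empty analysis window")
  }
  ms_per_sample <- 1000 / sample_rate
  nT <- length(times)
  per_train <- matrix(NA_real_, length(masks), nT)
  per_subject_mean <- numeric(length(masks))
  for (s in seq_along(masks)) {
    m <- masks[[s]]
    if (!is.matrix(m) || any(dim(m) != nT))
      stop("each mask must be a square matrix matching the time grid")
    dsig <- diag(m)
    win <- window
    if (is.null(win)) {
      if (!any(dsig)) {
        per_train[s, ] <- 0
        per_subject_mean[s] <- 0
        next
      }
      win <- range(times[dsig])
    }
    inwin <- times >= win[1L] & times <= win[2L]
    counts <- rowSums(m[, inwin, drop = FALSE])
    per_train[s, inwin] <- counts[inwin] * ms_per_sample
    use <- inwin & dsig
    per_subject_mean[s] <- if (any(use))
      mean(counts[use]) * ms_per_sample else 0
  }
  structure(list(per_train_ms = per_train,
                 per_subject_mean_ms = per_subject_mean,
                 mean_ms = mean(per_subject_mean),
                 times = times, window = window,
                 ms_per_sample = ms_per_sample),
            class = "tg_duration")
}

#' @export
print.tg_duration <- function(x, ...) {
  cat(sprintf(
    "<tg_duration> mean significant generalization: %.0f ms (%.1f samples)\n",
    x$mean_ms, x$mean_ms / x$ms_per_sample))
  invisible(x)
}

#' Diagonal versus generalization contrast at one training time
#'
#' For a fixed training time `t`, pairs each subject's generalization
#' performance `AUC(t, t')` with the diagonal performance `AUC(t', t')` at
#' every test time, giving the paired differences used to test where a
#' classifier's generalization deviates from the local code at that moment.
#'
#' @param tgms list of per-subject [tgm()] objects.
#' @param train_time training time in seconds (must lie on the grid).
#' @return List with `differences` (subjects x test-times matrix of
#'   `AUC(t, t') - AUC(t', t')`), `test_times`, `train_time`, `n_subjects`.
#' @export
diag_offdiag_contrast <- function(tgms, train_time) {
  stopifnot(length(tgms) >= 2L, all(vapply(tgms, inherits, TRUE, "tgm")))
  tt <- tgms[[1L]]$train_times
  ti <- time_index(tt, train_time)
  diffs <- t(vapply(tgms, function(x) x$auc[ti, ] - diag(x$auc),
                    numeric(length(tt))))
  list(differences = diffs, test_times = tt, train_time = tt[ti],
       n_subjects = length(tgms))
}

#' Diagonal versus anti-generalization comparison
#'
#' Compares, across subjects, the diagonal performance `AUC(t, t)` with the
#' reversed generalization performance `1 - AUC(t, t')` at a below-chance
#' cell, using the paired Wilcoxon signed-rank test. A significant positive
#' difference indicates the reversal is partial (the flipped pattern carries
#' less information than the original), as opposed to a pure polarity
#' inversion of one pattern.
#'
#' @param tgms list of per-subject [tgm()] objects.
#' @param t diagonal (training) time in seconds.
#' @param t_prime generalization (test) time in seconds.
#' @return An `htest` from [across_subject_test()] on the paired differences
#'   `AUC(t, t) - (1 - AUC(t, t'))`, with the differences attached.
#' @export
anti_generalization_contrast <- function(tgms, t, t_prime) {
  stopifnot(length(tgms) >= 2L, all(vapply(tgms, inherits, TRUE, "tgm")))
  tt <- tgms[[1L]]$train_times
  ti <- time_index(tt, t)
  tj <- time_index(tgms[[1L]]$test_times, t_prime)
  diag_perf <- vapply(tgms, function(x) x$auc[ti, ti], numeric(1))
  anti_perf <- vapply(tgms, function(x) 1 - x$auc[ti, tj], numeric(1))
  ht <- across_subject_test(diag_perf - anti_perf, null_value = 0)
  ht$method <- paste("Diagonal vs anti-generalization:", ht$method)
  ht$data.name <- sprintf("AUC(t,t) vs 1 - AUC(t,t') at t = %g s, t' = %g s",
                          tt[ti], tt[tj])
  ht$differences <- diag_perf - anti_perf
  ht
}
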