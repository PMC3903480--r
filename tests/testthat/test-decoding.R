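make_fake_contrast <- function(subclass, y = NULL) {
  subclass <- factor(subclass)
  if (is.null(y))
    y <- ifelse(grepl("^LD", as.character(subclass)), 1, -1)
  structure(list(name = "local", trials = seq_along(y), y = y,
                 subclass = subclass,
                 n_deviant = sum(y > 0), n_standard = sum(y < 0)),
            class = "contrast_spec")
}

test_that("stratified folds preserve subclass proportions", {
  # canonical session: subclass counts 300/300/90/90 divide evenly by k = 10
  lab <- localglobal_session(seed = 2)
  ep <- epochs_set(array(0, c(nrow(lab), 1, 2)), c(0, 1 / 256), 256, lab)
  ct <- make_contrast(ep, "global")
  fa <- stratified_folds(ct, k = 10, seed = 5)
  for (f in 1:10) {
    sel <- fa$fold == f
    expect_identical(sum(ct$y[sel] < 0), 60L)   # global standards per fold
    expect_identical(sum(ct$y[sel] > 0), 18L)   # global deviants per fold
  }
  # per-subclass proportions within one trial of exact in the general case
  ct2 <- make_fake_contrast(rep(c("LSGS", "LDGD", "LDGS"), c(23, 17, 31)))
  fa2 <- stratified_folds(ct2, k = 4, seed = 1)
  for (s in levels(ct2$subclass)) {
    per_fold <- tabulate(fa2$fold[ct2$subclass == s], 4)
    expect_lte(diff(range(per_fold)), 1L)
  }
  # determinism
  expect_identical(stratified_folds(ct2, k = 4, seed = 1)$fold, fa2$fold)
})

test_that("two subclasses of ten trials split one-plus-one over ten folds", {
  ct <- make_fake_contrast(rep(c("LSGS", "LDGD"), each = 10))
  fa <- stratified_folds(ct, k = 10, seed = 3)
  for (f in 1:10)
    expect_identical(as.integer(table(ct$subclass[fa$fold == f])), c(1L, 1L))
})

test_that("a subclass smaller than k is rejected by name", {
  ct <- make_fake_contrast(rep(c("LSGS", "LDGD"), c(20, 5)))
  expect_error(stratified_folds(ct, k = 10, seed = 1), "LDGD")
})

test_that("subclass weights equalize each category's total contribution", {
  ct <- make_fake_contrast(rep(c("LSGS", "LDGS", "LSGD", "LDGD"),
                               c(300, 300, 90, 90)))
  w <- subclass_weights(ct)
  totals <- as.numeric(tapply(w, ct$subclass, sum))
  expect_equal(totals, rep(780 / 4, 4), tolerance = 1e-12)
  # per-trial weights in ratio 1/300 : 1/90 between large and small subclasses
  w_lsgs <- w[ct$subclass == "LSGS"][1]
  w_ldgd <- w[ct$subclass == "LDGD"][1]
  expect_equal(w_ldgd / w_lsgs, 300 / 90, tolerance = 1e-12)

  ct_eq <- make_fake_contrast(rep(c("LSGS", "LDGD"), each = 10))
  expect_true(all(subclass_weights(ct_eq) == 1))
  ct_one <- make_fake_contrast(rep("LSGS", 8), y = rep(c(-1, 1), 4))
  expect_true(all(subclass_weights(ct_one) == 1))
})

test_that("normalization is estimated from training data only", {
  set.seed(7)
  tr <- matrix(rnorm(40 * 6), 40, 6)
  nz <- fit_normalizer(tr)
  z <- apply_normalizer(nz, tr)
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 6), tolerance = 1e-12)
  # a shifted held-out set is NOT re-centered: no leakage of test statistics
  te <- matrix(rnorm(10 * 6), 10, 6) + 3
  expect_gt(min(colMeans(apply_normalizer(nz, te))), 1)
  # constant channel maps to zeros rather than dividing by zero
  tr[, 2] <- 5
  z2 <- apply_normalizer(fit_normalizer(tr), tr)
  expect_true(all(z2[, 2] == 0))
})

test_that("the weighted linear SVM matches libsvm on equal weights", {
  skip_if_not_installed("e1071")
  set.seed(12)
  for (rep in 1:3) {
    X <- matrix(rnorm(50 * 8), 50, 8)
    y <- ifelse(X[, 1] - X[, 2] + rnorm(50, sd = 0.8) > 0, 1, -1)
    if (!any(y > 0) || !any(y < 0)) next
    fit <- tgdecode:::.svm_linear_fit_cpp(X, y, rep(1, 50))
    m <- e1071::svm(X, factor(y, levels = c(-1, 1)), kernel = "linear",
                    cost = 1, scale = FALSE)
    dv <- as.vector(attr(predict(m, X, decision.values = TRUE),
                         "decision.values"))
    ours <- as.vector(X %*% fit$w + fit$b)
    s <- sign(sum(dv * ours))
    expect_lt(max(abs(s * dv - ours)), 0.02)
    expect_true(fit$converged)
  }
})

test_that("training weights tilt the hyperplane toward heavy samples", {
  # two interleaved groups: upweighting one group must move the boundary
  set.seed(3)
  X <- rbind(matrix(rnorm(30 * 2, mean = 1), 30, 2),
             matrix(rnorm(30 * 2, mean = -1), 30, 2))
  y <- rep(c(1, -1), each = 30)
  w_uniform <- rep(1, 60)
  w_tilted <- c(rep(4, 30), rep(0.25, 30))
  f1 <- tgdecode:::.svm_linear_fit_cpp(X, y, w_uniform)
  f2 <- tgdecode:::.svm_linear_fit_cpp(X, y, w_tilted)
  expect_false(isTRUE(all.equal(f1$b, f2$b, tolerance = 1e-4)))
})

test_that("timepoint models separate a separable toy problem", {
  X <- rbind(matrix(c(2, 2), 10, 2, byrow = TRUE) + 0.1 * matrix(rnorm(20), 10),
             matrix(c(-2, -2), 10, 2, byrow = TRUE) + 0.1 * matrix(rnorm(20), 10))
  y <- rep(c(1, -1), each = 10)
  m <- train_timepoint(X, y)
  expect_equal(auc(decision_values(m, X), y), 1)
  p <- predict_probability(m, X)
  expect_true(all(p > 0 & p < 1))
  expect_gt(min(p[y > 0]), 0.8)     # calibrated probabilities cluster
  expect_lt(max(p[y < 0]), 0.2)
  expect_error(train_timepoint(X, rep(1, 20)), "single class")
})

test_that("the decision function is antisymmetric under joint negation", {
  set.seed(21)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- rep(c(1, -1), 15)
  m1 <- train_timepoint(X, y)
  m2 <- train_timepoint(-X, -y)
  expect_equal(decision_values(m2, -X), -decision_values(m1, X),
               tolerance = 1e-6)
})

test_that("probabilities are monotone in the decision value", {
  set.seed(22)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- ifelse(X[, 1] + rnorm(40, sd = 0.5) > 0, 1, -1)
  m <- train_timepoint(X, y)
  Xnew <- matrix(rnorm(25 * 3), 25, 3)
  d <- decision_values(m, Xnew)
  p <- predict_probability(m, Xnew)
  expect_identical(order(d), order(p))
  expect_error(predict_probability(m, Xnew[, 1:2]), "channels")
})

test_that("a symmetric balanced problem puts the boundary at p = 0.5", {
  X <- rbind(c(1, 0), c(-1, 0), c(2, 1), c(-2, -1), c(2, -1), c(-2, 1))
  X <- rbind(X, -X)  # fully symmetric design
  y <- rep(c(1, -1, 1, -1, 1, -1), 2)
  y[7:12] <- -y[1:6]
  m <- train_timepoint(X, y)
  expect_equal(predict_probability(m, matrix(0, 1, 2))[1], 0.5,
               tolerance = 1e-3)
})

test_that("auc matches hand-computed and brute-force values", {
  expect_equal(auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, -1, -1)), 1)
  expect_equal(auc(rep(0.5, 10), rep(c(1, -1), 5)), 0.5)
  expect_equal(auc(c(0.8, 0.6, 0.7, 0.1), c(1, 1, -1, -1)), 0.75)
  expect_error(auc(1:4, rep(1, 4)), "both classes")
  set.seed(31)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    y <- c(1, -1, sample(c(-1, 1), n - 2, replace = TRUE))
    expect_identical(auc(scores, y), auc_bruteforce(scores, y))
  }
})

test_that("auc is invariant to monotone transforms and flips with class", {
  set.seed(32)
  s <- rnorm(30)
  y <- rep(c(1, -1), 15)
  expect_equal(auc(exp(s), y), auc(s, y))
  expect_equal(auc(2 * s + 7, y), auc(s, y))
  expect_identical(auc(s, y) + auc(s, -y), 1)
})

test_that("decoding pure-noise labels stays at chance on average", {
  # stratified folds, as in the pipeline: class proportions are balanced in
  # every fold, which is what keeps cross-validated null decoding unbiased
  set.seed(33)
  aucs <- replicate(100, {
    X <- matrix(rnorm(50 * 6), 50, 6)
    y <- sample(rep(c(1, -1), 25))
    fold <- integer(50)
    fold[y > 0] <- sample(rep(1:10, length.out = 25))
    fold[y < 0] <- sample(rep(1:10, length.out = 25))
    p <- numeric(50)
    for (f in 1:10) {
      m <- train_timepoint(X[fold != f, ], y[fold != f])
      p[fold == f] <- predict_probability(m, X[fold == f, , drop = FALSE])
    }
    auc(p, y)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})
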