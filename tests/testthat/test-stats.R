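test_that("the Mann-Whitney U statistic is the AUC times n1 n2", {
  set.seed(41)
  for (i in 1:20) {
    n1 <- sample(3:15, 1); n2 <- sample(3:15, 1)
    s <- sample(seq(0, 1, 0.05), n1 + n2, replace = TRUE)  # with ties
    y <- rep(c(1, -1), c(n1, n2))
    ht <- within_subject_test(s, y)
    expect_equal(unname(ht$statistic), auc(s, y) * n1 * n2, tolerance = 1e-12)
    expect_equal(unname(ht$estimate), auc(s, y), tolerance = 1e-12)
  }
})

test_that("identical score distributions sit at the null center", {
  s <- rep(0.4, 12)
  y <- rep(c(1, -1), 6)
  ht <- within_subject_test(s, y)
  expect_equal(unname(ht$statistic), 6 * 6 / 2)
  expect_gt(ht$p.value, 0.95)
  expect_error(within_subject_test(1:5, rep(1, 5)), "both classes")
})

test_that("complete separation at n1 = n2 = 5 gives the exact floor p", {
  # enumeration oracle: 2 / choose(10, 5) = 2/252 for the two-sided test
  ht <- within_subject_test(c(6:10, 1:5), rep(c(1, -1), each = 5))
  expect_equal(ht$p.value, 2 / 252, tolerance = 1e-12)
})

test_that("the vectorized Mann-Whitney map matches wilcox.test", {
  set.seed(42)
  pos <- rep(c(TRUE, FALSE), c(12, 14))
  P <- matrix(sample(seq(0, 1, 0.1), 26 * 40, replace = TRUE), 26, 40)
  p_map <- tgdecode:::mw_p_columns(P, pos)
  p_ref <- apply(P, 2, function(s)
    suppressWarnings(stats::wilcox.test(s[pos], s[!pos], exact = FALSE,
                                        correct = TRUE))$p.value)
  expect_equal(p_map, p_ref, tolerance = 1e-12)
})

test_that("nine uniformly positive subjects give the exact signed-rank floor", {
  vals <- 0.5 + (1:9) / 100
  ht <- across_subject_test(vals, null_value = 0.5)
  expect_identical(ht$p.value, 2 / 512)
  expect_identical(ht$direction, 1)
  expect_match(ht$method, "exact")
})

test_that("signed-rank behaviour at the null and degenerate input", {
  vals <- 0.5 + c(-4, -3, -2, -1, 1, 2, 3, 4) / 100
  expect_gt(across_subject_test(vals, 0.5)$p.value, 0.9)
  expect_warning(ht <- across_subject_test(rep(0.5, 6), 0.5), "zero")
  expect_identical(ht$p.value, 1)
  expect_error(across_subject_test(0.6, 0.5), "at least 2")
})

test_that("signed-rank p-values match wilcox.test when the ranks are untied", {
  set.seed(43)
  for (i in 1:10) {
    x <- rnorm(12, 0.55, 0.1)
    x <- x[x != 0.5]
    ours <- across_subject_test(x, 0.5)
    ref <- stats::wilcox.test(x, mu = 0.5, exact = TRUE)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
  }
})

test_that("tied differences use the exact sign-flip null, not an approximation", {
  # brute-force oracle: enumerate all 2^n sign patterns of the midranks
  brute_p <- function(d) {
    r <- rank(abs(d))
    n <- length(d)
    V <- sum(r[d > 0])
    W <- vapply(0:(2^n - 1), function(m) {
      sgn <- as.integer(intToBits(m))[1:n]
      sum(r[sgn == 1])
    }, numeric(1))
    min(1, 2 * min(mean(W <= V), mean(W >= V)))
  }
  # binary-exact differences so 0.5 + d - 0.5 reproduces d and its ties
  cases <- list(rep(0.5, 10),                       # all tied (AUC = 1 stack)
                c(0.5, 0.5, 0.5, -0.5, 0.25, 0.25, 0.125, -0.125),
                c(0.375, 0.375, 0.25, 0.25, 0.25, -0.25, 0.125))
  for (d in cases) {
    ours <- across_subject_test(0.5 + d, 0.5)
    expect_equal(ours$p.value, brute_p(d), tolerance = 1e-12)
  }
  # the fully consistent stack of ten subjects hits the 2/1024 floor
  expect_identical(across_subject_test(rep(1, 10), 0.5)$p.value, 2 / 1024)
})

test_that("Benjamini-Hochberg step-up rejects per the hand-computed rule", {
  out <- fdr_correct(c(0.01, 0.02, 0.03, 0.04, 0.05), q = 0.05)
  expect_true(all(out$mask))       # p_(i) <= i * 0.01 for every i
  expect_identical(out$threshold, 0.05)

  expect_true(fdr_correct(0.04, q = 0.05)$mask)
  expect_false(any(fdr_correct(rep(1, 20), q = 0.05)$mask))
  expect_length(fdr_correct(numeric(0), q = 0.05)$mask, 0L)
  # mixed case: rejection set is contiguous in the sorted order
  out2 <- fdr_correct(c(0.001, 0.2, 0.013, 0.9, 0.021, 0.5), q = 0.05)
  expect_identical(out2$mask, c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
})

test_that("BH controls the empirical false discovery rate under the null", {
  set.seed(44)
  fdp <- replicate(500, {
    p <- runif(40)
    m <- fdr_correct(p, q = 0.05)$mask
    if (any(m)) 1 else 0   # all discoveries are false under the global null
  })
  tol <- 3 * sqrt(0.05 * 0.95 / 500)
  expect_lte(mean(fdp), 0.05 + tol)
})

test_that("group statistics flag a shifted stack and spare a null one", {
  set.seed(45)
  shift <- matrix(0, 6, 6)
  shift[2:4, 2:4] <- 0.3
  tgms <- lapply(1:10, function(s)
    fake_tgm(0.5 + shift + matrix(rnorm(36, sd = 0.01), 6, 6)))
  gs <- tgm_group_stats(tgms, q = 0.05)
  expect_true(all(gs$mask[2:4, 2:4]))
  expect_false(any(gs$mask[5:6, 5:6]))
  expect_equal(gs$mean_auc[3, 3], mean(sapply(tgms, function(x) x$auc[3, 3])))
  expect_output(print(gs), "significant cells")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(gs))
  expect_silent(plot(gs, what = "mask"))
})

test_that("within-subject maps flag informative cells via trial statistics", {
  ep <- quick_subject(sustained_scenario(12, 4, n_samples = 20), snr = 3,
                      seed = 46)
  fit <- tgm(ep, "local", k = 5, seed = 2)
  wm <- within_subject_map(fit, q = 0.05)
  expect_true(all(wm$mask[7:14, 7:14]))
  expect_lt(mean(wm$mask[c(1:4, 17:20), c(1:4, 17:20)]), 0.3)
})

test_that("generalization duration counts significant samples in the window", {
  times <- (0:99) / 256
  m <- matrix(FALSE, 100, 100)
  m[3:97, 3:97] <- TRUE
  d <- generalization_duration(m, times, 256, window = c(times[3], times[97]))
  expect_equal(unname(d$per_train_ms[1, 3:97]), rep(95 * 1000 / 256, 95))
  expect_equal(d$mean_ms, 95 * 1000 / 256)

  none <- generalization_duration(matrix(FALSE, 100, 100), times, 256)
  expect_identical(none$mean_ms, 0)
  expect_error(generalization_duration(m, times, 256, window = c(0.9, 1.0)),
               "empty")
})

test_that("per-subject masks average into a group duration", {
  times <- (0:9) / 256
  m1 <- matrix(FALSE, 10, 10); m1[2:5, 2:5] <- TRUE   # 4 samples each
  m2 <- matrix(FALSE, 10, 10); m2[2:5, 2:7] <- TRUE   # 6 samples each
  d <- generalization_duration(list(m1, m2), times, 256,
                               window = c(times[2], times[8]))
  expect_equal(d$per_subject_mean_ms, c(4, 6) * 1000 / 256)
  expect_equal(d$mean_ms, 5 * 1000 / 256)
})

test_that("diagonal-versus-generalization differences vanish for square TGMs", {
  sq <- matrix(0.8, 5, 5)
  tgms <- lapply(1:3, function(i) fake_tgm(sq))
  dc <- diag_offdiag_contrast(tgms, train_time = tgms[[1]]$train_times[2])
  expect_true(all(dc$differences == 0))
  expect_error(diag_offdiag_contrast(tgms, train_time = 0.5), "grid")
})

test_that("anti-generalization contrast distinguishes full from partial reversal", {
  times <- (0:5) / 256
  # full reversal: AUC(t,t') = 1 - AUC(t,t) for every subject -> differences 0
  full <- lapply(1:6, function(i) {
    a <- matrix(0.5, 6, 6)
    a[2, 2] <- 0.9
    a[2, 5] <- 0.1
    fake_tgm(a, times)
  })
  expect_warning(ht <- anti_generalization_contrast(full, times[2], times[5]),
                 "zero")
  expect_identical(ht$p.value, 1)
  # attenuated second segment: diagonal beats anti-generalization
  part <- lapply(1:8, function(i) {
    a <- matrix(0.5, 6, 6)
    a[2, 2] <- 0.9 + i / 1000
    a[2, 5] <- 0.3
    fake_tgm(a, times)
  })
  ht2 <- anti_generalization_contrast(part, times[2], times[5])
  expect_lt(ht2$p.value, 0.05)
  expect_identical(ht2$direction, 1)
})
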