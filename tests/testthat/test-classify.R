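test_that("linearly separable clusters are perfectly resolved in sample", {
  set.seed(1)
  x <- rbind(matrix(stats::rnorm(60, 0), ncol = 2),
             matrix(stats::rnorm(60, 6), ncol = 2))
  y <- rep(c(0, 1), each = 30)
  sc <- train_linear_svm(x, y)
  expect_true(all(sc[y == 1] > 0) && all(sc[y == 0] < 0))
  # flipping the labels flips the decision scores
  sc2 <- train_linear_svm(x, 1 - y)
  expect_equal(sc2, -sc, tolerance = 1e-6)
  expect_error(train_linear_svm(x, rep(1, 60)), "both classes")
})

test_that("the SVM boundary aligns with the Fisher discriminant", {
  set.seed(2)
  n <- 200
  x <- rbind(cbind(stats::rnorm(n, 0, 1), stats::rnorm(n, 0, 2)),
             cbind(stats::rnorm(n, 2.5, 1), stats::rnorm(n, 1.5, 2)))
  y <- rep(c(0, 1), each = n)
  xs <- scale(x)
  # closed-form LDA direction on the same standardized sample
  s_pool <- (stats::cov(xs[y == 0, ]) + stats::cov(xs[y == 1, ])) / 2
  w_lda <- solve(s_pool, colMeans(xs[y == 1, ]) - colMeans(xs[y == 0, ]))
  # recover the SVM normal from the decision scores (linear model fit)
  sc <- train_linear_svm(x, y)
  w_svm <- stats::coef(stats::lm(sc ~ xs))[-1]
  ang <- acos(sum(w_lda * w_svm) /
                sqrt(sum(w_lda^2) * sum(w_svm^2))) * 180 / pi
  expect_lt(ang, 5)
})

test_that("ROC handles perfect, uninformative and tied score sets", {
  r <- roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$op_sensitivity, 1)
  expect_equal(r$op_specificity, 1)
  r0 <- roc_auc(rep(2, 10), rep(c(0, 1), 5))
  expect_equal(r0$auc, 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("trapezoidal AUC equals pairwise concordance, including ties", {
  set.seed(5)
  for (i in 1:30) {
    n <- sample(10:40, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    sc <- round(stats::rnorm(n), 1)  # coarse scores force ties
    r <- roc_auc(sc, y)
    pos <- sc[y == 1]; neg <- sc[y == 0]
    conc <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(r$auc, mean(conc), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  y <- sample(0:1, 60, replace = TRUE, prob = c(0.5, 0.5))
  y[1:2] <- 0:1
  sc <- stats::rnorm(60) + y
  r <- roc_auc(sc, y)
  ref <- suppressMessages(as.numeric(pROC::auc(y, sc)))
  expect_equal(r$auc, ref, tolerance = 1e-10)
})

test_that("the operating point is invariant to monotone score transforms", {
  set.seed(7)
  y <- sample(0:1, 40, replace = TRUE); y[1:2] <- 0:1
  sc <- stats::rnorm(40) + 0.8 * y
  a <- roc_auc(sc, y)
  b <- roc_auc(exp(2 * sc) + 5, y)
  expect_equal(a$auc, b$auc, tolerance = 1e-12)
  expect_equal(a$op_sensitivity, b$op_sensitivity)
  expect_equal(a$op_specificity, b$op_specificity)
})

test_that("Mann-Whitney exact enumeration matches known cases", {
  r <- mann_whitney_two_sided(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_equal(r$p_value, 0.1)
  expect_match(r$method, "exact")
  same <- mann_whitney_two_sided(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$p_value, 1)
  expect_error(mann_whitney_two_sided(numeric(0), 1:3), "nonempty")
})

test_that("exact enumeration matches the reference implementation", {
  set.seed(8)
  for (i in 1:20) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- stats::rnorm(na); b <- stats::rnorm(nb, 0.5)
    ours <- mann_whitney_two_sided(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_equal(ours$u, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("the normal approximation tracks the exact tail", {
  set.seed(9)
  diffs <- replicate(40, {
    a <- stats::rnorm(8); b <- stats::rnorm(8, 0.7)
    pe <- mann_whitney_two_sided(a, b, exact_max = 8)$p_value
    pa <- mann_whitney_two_sided(a, b, exact_max = 0)$p_value
    abs(pe - pa)
  })
  expect_lt(max(diffs), 0.02)
})

test_that("pipeline evaluation hits the null band and saturates when separated", {
  set.seed(10)
  null_rec <- generate_scan(field = injury_field(core_severity = 0), seed = 30)
  # in the two-feature model the in-sample optimism is small; the
  # 16-feature model is checked out of sample (cross-validated)
  r <- evaluate_pipeline(null_rec, "one_channel")[[1]]
  expect_gt(r$auc, 0.35); expect_lt(r$auc, 0.65)
  rc <- evaluate_pipeline(null_rec, "four_channel", "k_fold")[[1]]
  expect_gt(rc$auc, 0.35); expect_lt(rc$auc, 0.65)
  big <- generate_scan(params = generator_params(dep_ipsi = 0.14 + 5 * 0.05,
                                                 noise_sd = 0),
                       field = injury_field(decay_length_mm = 1e3), seed = 31)
  rb <- evaluate_pipeline(big, "one_channel")[[1]]
  expect_gt(rb$auc, 0.99)
  # determinism of the evaluation
  r2 <- evaluate_pipeline(null_rec, "one_channel")[[1]]
  expect_identical(r$auc, r2$auc)
})

test_that("k-fold cross-validation runs and stays below resubstitution optimism", {
  rec <- generate_scan(seed = 33)
  ft <- feature_table(rec)
  rcv <- evaluate_pipeline(ft, "four_channel", "k_fold", fold_seed = 2)[[1]]
  rrs <- evaluate_pipeline(ft, "four_channel", "resubstitution")[[1]]
  expect_true(rcv$auc >= 0.5 && rcv$auc <= 1)
  expect_gte(rrs$auc, rcv$auc - 0.1)
})
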