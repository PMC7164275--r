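test_that("AUC handles separation, ties, and matches exhaustive pair counting", {
  expect_equal(auc_mann_whitney(c(1, 2, 10, 20), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auc_mann_whitney(rep(3, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  set.seed(14)
  for (rep in 1:30) {
    n <- sample(6:14, 1)
    scores <- sample(0:5, n, replace = TRUE) # many ties
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    expect_equal(auc_mann_whitney(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(auc_mann_whitney(1:4, rep(TRUE, 4)), class = "rhinorep_error_degenerate")
})

test_that("DeLong variance equals the explicit placement-value oracle", {
  scores <- c(0.1, 0.5, 0.4, 0.9, 0.8, 0.35, 0.55, 0.2, 0.95, 0.6)
  labels <- c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  res <- delong_ci(scores, labels)
  expect_equal(res$auc, oracle_auc(scores, labels), tolerance = 1e-12)
  expect_equal(res$delong_se^2, oracle_delong_var(scores, labels), tolerance = 1e-12)
  expect_true(res$ci95[1] <= res$auc && res$auc <= res$ci95[2])
})

test_that("DeLong results are invariant under monotone score transforms", {
  set.seed(15)
  scores <- rnorm(40)
  labels <- rep(c(TRUE, FALSE), 20)
  a <- delong_ci(scores, labels)
  b <- delong_ci(exp(scores), labels)
  expect_equal(a$auc, b$auc, tolerance = 1e-12)
  expect_equal(a$delong_se, b$delong_se, tolerance = 1e-12)
  expect_equal(a$ci95, b$ci95, tolerance = 1e-12)
})

test_that("DeLong AUC and variance agree with the pROC cross-check", {
  skip_if_not_installed("pROC")
  set.seed(16)
  scores <- rnorm(60)
  labels <- scores + rnorm(60) > 0
  ours <- delong_ci(scores, labels)
  ref <- pROC::roc(response = labels, predictor = scores, quiet = TRUE,
                   direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  expect_equal(ours$delong_se^2, as.numeric(pROC::var(ref)), tolerance = 1e-10)
})

test_that("perfect separation collapses the interval and flags it", {
  res <- delong_ci(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3))
  expect_true(res$collapsed)
  expect_equal(res$ci95, c(1, 1))
})

test_that("cross-validated AUC is stratified, deterministic, and consistent", {
  scores <- c(1:10, 101:110)
  labels <- rep(c(FALSE, TRUE), each = 10)
  cv <- cross_validated_auc(scores, labels, folds = 5, seed = 2)
  expect_equal(as.numeric(cv), 1)
  expect_equal(attr(cv, "fold_auc"), rep(1, 5))
  expect_identical(cross_validated_auc(scores, labels, folds = 5, seed = 2),
                   cross_validated_auc(scores, labels, folds = 5, seed = 2))
  expect_error(cross_validated_auc(scores, c(rep(FALSE, 17), rep(TRUE, 3)),
                                   folds = 5),
               class = "rhinorep_error_design")
  # large-sample consistency with the full-sample AUC
  set.seed(17)
  s2 <- rnorm(500)
  l2 <- s2 + rnorm(500, sd = 1.5) > 0
  full <- auc_mann_whitney(s2, l2)
  cv2 <- as.numeric(cross_validated_auc(s2, l2, folds = 5, seed = 3))
  expect_lt(abs(cv2 - full), 0.05)
})

test_that("the pipeline ROC table reports both full-sample and cross-validated AUC", {
  d <- make_fixture("paper_scale")
  rt <- roc_table(d, folds = 5, seed = 1)
  expect_identical(nrow(rt), 12L) # 4 parameters x 3 scales
  expect_true(all(rt$auc >= 0 & rt$auc <= 1))
  expect_true(all(rt$ci_low <= rt$auc & rt$auc <= rt$ci_high))
  expect_true(all(is.finite(rt$cv_auc)))
  # resistance should predict symptoms better than chance on this design
  expect_gt(mean(rt$auc), 0.5)
})
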