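test_that("one-way ANOVA components match the explicit sums-of-squares oracle", {
  x <- rbind(c(1, 2), c(2, 4), c(3, 6), c(4, 8))
  vc <- anova_oneway(x)
  o <- oracle_icc(x)
  expect_equal(vc$ms_between, o$msb, tolerance = 1e-12)
  expect_equal(vc$ms_within, o$msw, tolerance = 1e-12)
  expect_equal(vc$sigma2_within, vc$ms_within)
  expect_equal(vc$sigma2_between, (vc$ms_between - vc$ms_within) / 2)
  expect_equal(vc$df_between, 3L)
  expect_equal(vc$df_within, 4L)
  # against base R aov on the same layout
  long <- data.frame(v = as.vector(t(x)), s = factor(rep(1:4, each = 2)))
  tab <- summary(stats::aov(v ~ s, long))[[1]]
  expect_equal(vc$ms_between, tab["s", "Mean Sq"], tolerance = 1e-12)
  expect_equal(vc$ms_within, tab["Residuals", "Mean Sq"], tolerance = 1e-12)
})

test_that("degenerate tables decompose as expected", {
  vc <- anova_oneway(rbind(c(1, 1), c(2, 2), c(3, 3)))
  expect_equal(vc$ms_within, 0)
  expect_equal(vc$sigma2_within, 0)
  expect_gt(vc$ms_between, 0)
  vc0 <- anova_oneway(matrix(4, 3, 2))
  expect_equal(vc0$ms_between, 0)
  expect_equal(vc0$ms_within, 0)
})

test_that("icc_oneway matches the frozen brute-force oracle values", {
  x <- rbind(c(1, 3), c(2, 2), c(6, 4), c(5, 7))
  res <- icc_oneway(x, rho0 = 0.20)
  # frozen from the double-loop + F-density-integration oracle
  expect_equal(res$estimate, 0.7, tolerance = 1e-12)
  expect_equal(res$f_statistic, 3.77777777777778, tolerance = 1e-12)
  expect_equal(res$p_value, 0.115895155444356, tolerance = 1e-9)
  o <- oracle_icc(x)
  expect_equal(res$estimate, o$icc, tolerance = 1e-12)
  expect_equal(res$p_value, o$p, tolerance = 1e-9)
})

test_that("perfect within-subject agreement gives ICC 1 with p 0", {
  res <- icc_oneway(rbind(c(5, 5), c(7, 7), c(9, 9)))
  expect_equal(res$estimate, 1)
  expect_equal(res$f_statistic, Inf)
  expect_equal(res$p_value, 0)
  expect_identical(res$benchmark, "excellent")
  expect_error(icc_oneway(matrix(3, 3, 3)), class = "rhinorep_error_agreement_undefined")
})

test_that("the ICC estimate is invariant under affine rescaling", {
  set.seed(11)
  for (rep in 1:20) {
    x <- matrix(rnorm(5 * 3, mean = 10), 5, 3)
    base <- icc_oneway(x)$estimate
    shift <- runif(1, -50, 50)
    scale <- runif(1, 0.1, 20)
    expect_equal(icc_oneway(x + shift)$estimate, base, tolerance = 1e-9)
    expect_equal(icc_oneway(x * scale)$estimate, base, tolerance = 1e-9)
  }
})

test_that("with rho0 = 0 the test reduces to the classical one-way F-test", {
  set.seed(3)
  x <- matrix(rnorm(12, mean = rep(1:4, 3)), 4, 3)
  res <- icc_oneway(x, rho0 = 0)
  long <- data.frame(v = as.vector(x), s = factor(rep(1:4, 3)))
  tab <- summary(stats::aov(v ~ s, long))[[1]]
  expect_equal(res$f_statistic, tab["s", "F value"], tolerance = 1e-10)
  expect_equal(res$p_value, tab["s", "Pr(>F)"], tolerance = 1e-10)
})

test_that("balanced-data estimate equals the variance-component ratio when sigma2_between >= 0", {
  set.seed(8)
  for (rep in 1:20) {
    x <- matrix(rnorm(24, mean = rep(rnorm(6, sd = 2), times = 4)), 6, 4)
    vc <- anova_oneway(x)
    if (vc$sigma2_between >= 0) {
      expect_equal(icc_oneway(x)$estimate,
                   vc$sigma2_between / (vc$sigma2_between + vc$sigma2_within),
                   tolerance = 1e-12)
    }
  }
})

test_that("benchmark labels follow the half-open agreement scale", {
  expect_identical(icc_benchmark(0.15), "poor")
  expect_identical(icc_benchmark(0.81), "excellent")
  expect_identical(icc_benchmark(-0.05), "poor")
  expect_identical(
    icc_benchmark(c(0.20, 0.2000001, 0.40, 0.60, 0.80, 1)),
    c("poor", "fair", "fair", "moderate", "substantial", "excellent")
  )
  expect_error(icc_benchmark(1.2), class = "rhinorep_error_input")
})

test_that("input validation rejects bad designs and missing data", {
  expect_error(repeated_measures(matrix(1, 1, 5)), class = "rhinorep_error_design")
  expect_error(repeated_measures(cbind(1:4)), class = "rhinorep_error_design")
  expect_error(repeated_measures(rbind(c(1, NA), c(2, 3))), class = "rhinorep_error_input")
  expect_error(icc_oneway(rbind(c(1, 2), c(3, 4)), rho0 = 1), class = "rhinorep_error_input")
})
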