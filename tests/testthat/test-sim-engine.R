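# Reduced-size runs keep this file fast; the full default grids run in
# test-acceptance.R.

test_that("derive_sigma_w reproduces the printed grid column and round-trips", {
  expect_equal(derive_sigma_w(1, 0.10), 3, tolerance = 1e-12)
  expect_equal(round(derive_sigma_w(3, 0.40), 2), 3.67)
  expect_equal(derive_sigma_w(4, 0.5), 4)
  for (sb in c(1, 2, 3)) for (icc in seq(0.1, 0.9, by = 0.1)) {
    sw <- derive_sigma_w(sb, icc)
    expect_equal(sb^2 / (sb^2 + sw^2), icc, tolerance = 1e-12)
  }
  expect_error(derive_sigma_w(1, 1), class = "rhinorep_error_input")
  expect_error(derive_sigma_w(0, 0.5), class = "rhinorep_error_input")
})

test_that("identical seed and config give bit-identical grids", {
  cfg <- batch1_config(cv_grid = c(0.1, 0.5), replicates = 50, seed = 99)
  expect_identical(simulate_batch1(cfg), simulate_batch1(cfg))
  cfg2 <- batch2_config(gamma_grid = c(5, 10), sigma_b_grid = 1,
                        icc_grid = c(0.3, 0.7), replicates = 50, seed = 99)
  expect_identical(simulate_batch2(cfg2), simulate_batch2(cfg2))
})

test_that("per-cell substreams make cells independent of which others run", {
  full <- simulate_batch1(batch1_config(cv_grid = c(0.1, 0.3, 0.5),
                                        replicates = 40, seed = 7))
  # the first cell of any run with the same root seed is the same cell
  partial <- simulate_batch1(batch1_config(cv_grid = c(0.1, 0.9),
                                           replicates = 40, seed = 7))
  expect_identical(full$cells[1, ], partial$cells[1, ])
})

test_that("vectorised ICC estimates agree with icc_oneway per replicate", {
  set.seed(21)
  a <- array(rnorm(6 * 4 * 8, mean = 5), dim = c(6, 4, 8))
  est <- rhinorep:::icc_estimates_array(a)
  for (r in 1:8) {
    expect_equal(est[r], icc_oneway(a[, , r])$estimate, tolerance = 1e-12)
  }
})

test_that("batch-1 means track the closed-form design ICC at small-to-moderate CV", {
  cvs <- c(0.05, 0.11, 0.21, 0.31, 0.41)
  g <- simulate_batch1(batch1_config(cv_grid = cvs, replicates = 1000, seed = 31))
  mu <- seq(5, 8, length.out = 10)
  analytic <- var(mu) / (var(mu) + cvs^2 * mean(mu^2))
  # the ANOVA estimator carries a small negative bias (~0.01 at mid CV),
  # so the band is 3 MC SEs with a 0.015 absolute floor
  expect_true(all(abs(g$cells$mean_index - analytic) <
                    pmax(3 * g$cells$mc_se, 0.015)))
})

test_that("Monte-Carlo error shrinks like 1/sqrt(replicates)", {
  cvs <- c(0.2, 0.5, 0.8)
  g250 <- simulate_batch1(batch1_config(cv_grid = cvs, replicates = 250, seed = 17))
  g1000 <- simulate_batch1(batch1_config(cv_grid = cvs, replicates = 1000, seed = 18))
  ratio <- mean(g250$cells$mc_se) / mean(g1000$cells$mc_se)
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("batch-2 pooled CV approaches the delta-method value at large mean", {
  cfg <- batch2_config(gamma_grid = 10, sigma_b_grid = c(1, 3),
                       icc_grid = c(0.2, 0.5, 0.9), replicates = 400, seed = 23)
  g <- simulate_batch2(cfg)
  c2 <- g$cells
  expected <- sqrt(c2$sigma_b^2 + c2$sigma_w^2) / c2$gamma
  expect_true(all(abs(c2$mean_index - expected) <= pmax(0.02, 4 * c2$mc_se)))
})

test_that("per-subject estimator gives systematically smaller CVs than pooled", {
  cfg <- batch2_config(gamma_grid = 10, sigma_b_grid = 2, icc_grid = 0.5,
                       replicates = 300, seed = 29)
  pooled <- simulate_batch2(cfg, estimator = "pooled")$cells$mean_index
  per_subj <- simulate_batch2(cfg, estimator = "per_subject")$cells$mean_index
  expect_lt(per_subj, pooled)
})

test_that("parameter recovery: mean estimated ICC near truth under the mixed model", {
  true_icc <- 0.6
  cfg_n <- 40
  set.seed(41)
  est <- replicate(300, {
    mu <- rnorm(cfg_n, 10, 1)
    sw <- derive_sigma_w(1, true_icc)
    x <- matrix(rnorm(cfg_n * 5, mean = rep(mu, 5), sd = sw), cfg_n, 5)
    icc_oneway(x)$estimate
  })
  expect_lt(abs(mean(est) - true_icc), max(0.02, 4 * sd(est) / sqrt(300)))
})

test_that("grid_to_table produces the documented shapes and rejects mismatches", {
  g1 <- simulate_batch1(batch1_config(cv_grid = c(0.2, 0.4), replicates = 20, seed = 1))
  curve <- grid_to_table(g1, "icc_curve")
  expect_identical(names(curve), c("true_cv", "mean_icc"))
  expect_identical(nrow(curve), 2L)
  cfg2 <- batch2_config(gamma_grid = 1:3, sigma_b_grid = c(1, 2),
                        icc_grid = c(0.3, 0.6), replicates = 20, seed = 1)
  wide <- grid_to_table(simulate_batch2(cfg2), "cv_wide")
  expect_identical(nrow(wide), 4L) # 2 sigma_b x 2 icc
  expect_identical(ncol(wide), 3L + 3L) # keys + one column per gamma
  expect_error(grid_to_table(g1, "cv_wide"), class = "rhinorep_error_structure")
  expect_error(grid_to_table(list(), "icc_curve"), class = "rhinorep_error_structure")
})

test_that("config validation catches out-of-range grids", {
  expect_error(batch1_config(cv_grid = c(0.5, 1.2)), class = "rhinorep_error_config")
  expect_error(batch1_config(mu_grid = 1:5), class = "rhinorep_error_config")
  expect_error(batch2_config(icc_grid = 0), class = "rhinorep_error_config")
})
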