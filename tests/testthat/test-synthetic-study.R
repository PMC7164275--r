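test_that("generation is deterministic given seed and config", {
  a <- make_fixture("tiny", seed = 5)
  b <- make_fixture("tiny", seed = 5)
  expect_identical(a, b)
  c <- make_fixture("tiny", seed = 6)
  expect_false(identical(a$measurements$value, c$measurements$value))
})

test_that("TOT equals R + L for every record", {
  d <- make_fixture("tiny")
  m <- d$measurements
  key <- c("subject_id", "day", "parameter", "phase", "replicate")
  srt <- function(side) {
    sub <- m[m$side == side, ]
    sub[do.call(order, sub[key]), ]
  }
  r <- srt("R"); l <- srt("L"); tot <- srt("TOT")
  expect_equal(tot$value, r$value + l$value, tolerance = 1e-12)
})

test_that("lognormal mode emits strictly positive values; normal mode can go nonpositive", {
  d <- make_fixture("paper_scale")
  expect_true(all(d$measurements$value > 0))
  # SAR-D has SD larger than its mean: a normal model must produce
  # nonpositive values with non-negligible probability
  cfg <- study_config(groups = default_group_profiles()["SAR-D"],
                      n_per_group = 50, noise_family = "normal", seed = 3)
  dn <- generate_study(cfg)
  expect_true(any(dn$measurements$value <= 0))
})

test_that("the design matches the emulated study structure", {
  d <- make_fixture("paper_scale")
  expect_identical(nrow(d$subjects), 50L)
  m <- d$measurements
  expect_setequal(unique(m$day), c(0L, 14L, 28L))
  expect_setequal(unique(m$parameter), c("R2", "R75", "R100", "R150"))
  # per subject: 4 parameters x 2 phases x 3 sides x (5 baseline + 2 follow-ups)
  expect_identical(nrow(m), 50L * 4L * 2L * 3L * 7L)
  expect_identical(sort(unique(m$replicate[m$day == 0])), 1:5)
  expect_identical(unique(m$replicate[m$day > 0]), 1L)
})

test_that("symptom prevalence converges to the configured probability over seeds", {
  gp <- default_group_profiles()["HC"] # symptom_prob 0.60
  draws <- vapply(1:40, function(s) {
    d <- generate_study(study_config(groups = gp, n_per_group = 10, seed = s))
    sum(d$subjects$symptoms)
  }, numeric(1))
  n_total <- 40 * 10
  p_hat <- sum(draws) / n_total
  expect_lt(abs(p_hat - 0.60), 4 * sqrt(0.6 * 0.4 / n_total))
})

test_that("calibration: generated group means track the configured totals", {
  d <- make_fixture("recovery")
  for (g in c("HC", "PAR")) {
    mat <- visit1_matrix(d, g, "R2", "inspiratory", "TOT")
    target <- default_group_profiles()[[g]]$mean_total["R2", "inspiratory"]
    subject_means <- rowMeans(mat)
    se <- sd(subject_means) / sqrt(length(subject_means))
    expect_lt(abs(mean(subject_means) - target), 3 * se)
  }
})

test_that("recovered ICC ordering is monotone in the configured truth", {
  gp <- default_group_profiles()[c("HC", "NAR", "PAR")]
  gp$HC$true_icc <- 0.3; gp$NAR$true_icc <- 0.6; gp$PAR$true_icc <- 0.9
  d <- generate_study(study_config(groups = gp, n_per_group = 60,
                                   noise_family = "normal", seed = 13))
  est <- vapply(c("HC", "NAR", "PAR"), function(g) {
    icc_oneway(visit1_matrix(d, g, "R100", "inspiratory", "TOT"))$estimate
  }, numeric(1))
  expect_true(est["HC"] < est["NAR"] && est["NAR"] < est["PAR"])
})

test_that("with unit drift the between-day bias is centred at zero over seeds", {
  gp <- default_group_profiles()["PAR"] # day_drift is 1 for PAR
  biases <- vapply(1:25, function(s) {
    d <- generate_study(study_config(groups = gp, n_per_group = 10, seed = s))
    bd <- between_day_reproducibility(d)
    bd$bias[bd$parameter == "R2" & bd$day == 14]
  }, numeric(1))
  se <- sd(biases) / sqrt(length(biases))
  expect_lt(abs(mean(biases)), 4 * se + 0.05)
})

test_that("profile validation rejects infeasible calibrations", {
  expect_error(group_profile("X", matrix(-1, 4, 2), matrix(1, 4, 2), 0.5, 0.5),
               class = "rhinorep_error_config")
  expect_error(group_profile("X", matrix(1, 4, 2), matrix(1, 4, 2), 1.2, 0.5),
               class = "rhinorep_error_config")
  expect_error(study_config(n_per_group = 1), class = "rhinorep_error_config")
  expect_error(make_fixture("nope"))
})
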