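test_that("gumbel_probability hits its definitional landmarks", {
  expect_equal(gumbel_probability(-1, alpha = -1, slope = 2, lambda = 0.02),
               0.25 + (1 - 0.25 - 0.02) * (1 - exp(-1)))
  expect_equal(gumbel_probability(-50, -1, 2), 0.25)
  expect_equal(gumbel_probability(50, -1, 2, lambda = 0.03), 0.97)
  expect_error(gumbel_probability(0, 0, slope = -1), "positive")
})

test_that("bin_trials aggregates lattice amplitudes", {
  b <- bin_trials(c(0.1, 0.1, 0.2, 0.1, 0.2), c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(b$amplitude, c(0.1, 0.2))
  expect_equal(b$n_trials, c(3L, 2L))
  expect_equal(b$n_correct, c(2L, 2L))
})

test_that("refitting the model's own predictions reproduces the parameters", {
  amps <- 10^seq(-2, -0.6, length.out = 7)
  truth <- list(alpha = -1.35, slope = 1.8, lambda = 0.02)
  p <- gumbel_probability(log10(amps), truth$alpha, truth$slope,
                          0.25, truth$lambda)
  n <- 1e5
  d <- tibble::tibble(amplitude = amps, n_trials = n,
                      n_correct = round(n * p))
  fit <- fit_gumbel(d)
  expect_equal(fit$alpha, truth$alpha, tolerance = 1e-3)
  expect_equal(fit$slope, truth$slope, tolerance = 1e-2)
  expect_equal(fit$lambda, truth$lambda, tolerance = 1e-3)
})

test_that("separable step data put the threshold between the straddling amplitudes", {
  d <- tibble::tibble(
    amplitude = c(0.02, 0.04, 0.08, 0.16, 0.32),
    n_trials = 40L,
    n_correct = c(10L, 10L, 10L, 40L, 40L)
  )
  fit <- fit_gumbel(d)
  expect_gt(fit$threshold_amplitude, 0.08)
  expect_lt(fit$threshold_amplitude, 0.16)
})

test_that("degenerate all-correct data are flagged as boundary fits", {
  d <- tibble::tibble(amplitude = c(0.05, 0.1, 0.2), n_trials = 30L,
                      n_correct = c(30L, 30L, 30L))
  fit <- fit_gumbel(d)
  expect_true(fit$at_boundary)
  expect_error(fit_gumbel(d[1:2, ]), "at least 3")
})

test_that("threshold is equivariant under amplitude rescaling", {
  set.seed(21)
  d <- simulate_binned(-1.3, 2, 0.01, 10^seq(-1.9, -0.7, length.out = 6), 60)
  f1 <- fit_gumbel(d)
  d2 <- d
  d2$amplitude <- d2$amplitude * 3.7
  f2 <- fit_gumbel(d2)
  expect_equal(f2$threshold_amplitude / f1$threshold_amplitude, 3.7,
               tolerance = 1e-3)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-3)
})

test_that("well-behaved monotone data lose no points to the chi-square screen", {
  set.seed(22)
  d <- simulate_binned(-1.3, 2, 0, 10^seq(-1.9, -0.7, length.out = 7), 200)
  fit <- prune_top_points(d)
  expect_length(fit$removed_points, 0)
})

test_that("a top amplitude forced to chance is removed, and at most two ever are", {
  set.seed(23)
  amps <- 10^seq(-1.9, -0.5, length.out = 8)
  d <- simulate_binned(-1.3, 2.5, 0, amps, 120)
  d$n_correct[8] <- stats::rbinom(1, 120, 0.25) # unreliable top point
  fit <- prune_top_points(d)
  expect_equal(fit$removed_points, amps[8], tolerance = 1e-9)
  # deviance must have improved when the point was dropped
  full <- fit_gumbel(d)
  expect_lt(fit$deviance, full$deviance)

  d2 <- d
  d2$n_correct[7:8] <- stats::rbinom(2, 120, 0.25)
  fit2 <- prune_top_points(d2)
  expect_lte(length(fit2$removed_points), 2)
  # never removes below the 3-point floor
  d3 <- d2[c(1, 2, 6, 7, 8), ]
  fit3 <- prune_top_points(d3)
  expect_gte(nrow(fit3$data), 3)
})

test_that("bootstrap confidence intervals cover the generating threshold", {
  set.seed(24)
  amps <- 10^seq(-2, -0.6, length.out = 7)
  alpha_true <- -1.4
  cover <- vapply(1:60, function(i) {
    d <- simulate_binned(alpha_true, 2, 0.01, amps, 40)
    f <- tryCatch(fit_gumbel(d), error = function(e) NULL)
    if (is.null(f)) return(NA)
    ci <- bootstrap_psychfit(f, n_boot = 200)
    ci$alpha_lo <= alpha_true && alpha_true <= ci$alpha_hi
  }, logical(1))
  expect_gte(mean(cover, na.rm = TRUE), 0.85)
})

test_that("tidy and glance expose the psychometric fit", {
  set.seed(25)
  d <- simulate_binned(-1.3, 2, 0, 10^seq(-1.9, -0.7, length.out = 6), 80)
  fit <- fit_gumbel(d)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "fixed"))
  expect_equal(td$estimate[td$term == "gamma"], 0.25)
  g <- glance(fit)
  expect_equal(g$n_points, 6L)
  expect_s3_class(autoplot(fit), "ggplot")
})
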