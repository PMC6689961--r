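test_that("a noiseless observer always finds a clearly curved target", {
  set.seed(1)
  obs <- observer_params(sigma_int = 0, efficiency = 1, lapse = 0)
  for (i in 1:25) {
    stims <- make_trial_stimuli(0.25, noise_sd = 0)
    target <- which(vapply(stims, `[[`, logical(1), "is_valid"))
    expect_identical(decide_4afc(stims, obs), target)
  }
})

test_that("decide_4afc validates its preconditions", {
  set.seed(2)
  obs <- observer_params(1)
  stims <- make_trial_stimuli(0.1, 0)
  bad <- stims
  bad[[2]]$is_valid <- TRUE
  expect_error(decide_4afc(bad, obs), "exactly one")
  bad2 <- stims
  bad2[[3]]$amplitude <- 0.2
  expect_error(decide_4afc(bad2, obs), "share amplitude")
})

test_that("performance at zero amplitude is at the 4AFC chance level", {
  set.seed(3)
  obs <- observer_params(sigma_int = 3, efficiency = 1, lapse = 0)
  tab <- observer_psychometric(obs, 0, amplitudes = 0, n_per_point = 6000)
  se <- sqrt(0.25 * 0.75 / 6000)
  expect_lt(abs(tab$prop_correct - 0.25), 4 * se)
})

test_that("with four identical stimuli the choice distribution is uniform", {
  set.seed(4)
  obs <- observer_params(sigma_int = 2, efficiency = 1, lapse = 0)
  stims <- make_trial_stimuli(0, noise_sd = 0, target_quadrant = "UL")
  choices <- vapply(1:8000, function(i) decide_4afc(stims, obs), integer(1))
  p <- stats::chisq.test(tabulate(choices, 4))$p.value
  expect_gt(p, 0.001)
})

test_that("the fast trial path matches the full stimulus-level decision rule", {
  # two routes through the same decision model: explicit stimuli +
  # decide_4afc versus the vectorized kernel used by the pipeline
  obs <- observer_params(sigma_int = 4, efficiency = 1, lapse = 0)
  for (a in c(0.03, 0.08)) {
    set.seed(50 + round(1000 * a))
    slow <- observer_psychometric(obs, 8, a, n_per_point = 1500,
                                  full_stimuli = TRUE)$prop_correct
    fast <- observer_psychometric(obs, 8, a, n_per_point = 1500)$prop_correct
    se <- sqrt(2 * 0.5 * 0.5 / 1500)
    expect_lt(abs(slow - fast), 3.5 * se)
  }
})

test_that("accuracy is monotone in amplitude, internal noise and external noise", {
  set.seed(5)
  n <- 2500
  pc <- function(a, si, ne) {
    observer_psychometric(observer_params(si, 1, 0), ne, a, n)$prop_correct
  }
  se3 <- 3 * sqrt(0.5 * 0.5 / n) * sqrt(2)
  amp_curve <- vapply(c(0.01, 0.04, 0.12), pc, numeric(1), si = 4, ne = 8)
  expect_true(all(diff(amp_curve) > -se3))
  sig_curve <- vapply(c(1, 5, 12), function(s) pc(0.05, s, 0), numeric(1))
  expect_true(all(diff(sig_curve) < se3))
  ext_curve <- vapply(c(0, 8, 16), function(ne) pc(0.05, 4, ne), numeric(1))
  expect_true(all(diff(ext_curve) < se3))
})

test_that("doubling internal noise roughly doubles the zero-noise threshold", {
  set.seed(6)
  t3 <- simulate_tvn(observer_params(3, 1, 0), 0, n_staircases = 12)$threshold
  t6 <- simulate_tvn(observer_params(6, 1, 0), 0, n_staircases = 12)$threshold
  expect_gt(t6 / t3, 1.5)
  expect_lt(t6 / t3, 2.6)
})

test_that("observer thresholds follow the Linear Amplifier Model", {
  set.seed(7)
  grid <- expand.grid(sigma = c(3, 6), eff = c(0.5, 1))
  fits <- lapply(seq_len(nrow(grid)), function(i) {
    tvn <- simulate_tvn(observer_params(grid$sigma[i], grid$eff[i], 0),
                        c(0, 8, 16), n_staircases = 10)
    fit <- fit_lam(tvn$noise_sd, tvn$threshold)
    ly <- log10(tvn$threshold)
    r2 <- 1 - fit$rss_log / sum((ly - mean(ly))^2)
    list(fit = fit, r2 = r2)
  })
  for (i in seq_along(fits)) {
    expect_gt(fits[[i]]$r2, 0.95)
    expect_lt(abs(fits[[i]]$fit$sigma_internal - grid$sigma[i]) /
                grid$sigma[i], 0.25)
  }
  # beta increases with the pooling fraction at fixed internal noise
  beta_by_eff <- vapply(fits, function(f) f$fit$beta, numeric(1))
  expect_gt(beta_by_eff[3], beta_by_eff[1]) # sigma = 3
  expect_gt(beta_by_eff[4], beta_by_eff[2]) # sigma = 6
})

test_that("lapses cap asymptotic performance below one", {
  set.seed(8)
  obs <- observer_params(sigma_int = 0.5, efficiency = 1, lapse = 0.05)
  p <- observer_psychometric(obs, 0, 0.25, n_per_point = 4000)$prop_correct
  # expected 1 - lapse * 3/4
  expect_lt(abs(p - (1 - 0.05 * 3 / 4)), 3 * sqrt(0.04 * 0.96 / 4000))
})
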