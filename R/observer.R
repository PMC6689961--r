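#' Simulated equivalent-noise observer
#'
#' Parameters of the stochastic observer used to generate synthetic trial
#' data. The observer perceives each element's orientation corrupted by
#' independent internal noise (`sigma_int`, degrees of orientation), pools
#' evidence from a random subset of `ceiling(efficiency * n_wavelets)`
#' elements, and compares each quadrant's percept against the valid and
#' opposite-curvature orientation templates. Its thresholds as a function
#' of external noise follow the Linear Amplifier Model by construction:
#' the decision variable's signal-to-noise ratio scales as
#' amplitude / sqrt(sigma_ext^2 + sigma_int^2).
#'
#' @param sigma_int Internal orientation-noise SD per element, degrees >= 0.
#' @param efficiency Fraction of elements pooled, in (0, 1].
#' @param lapse Probability of a stimulus-independent random response,
#'   in \[0, 0.05\].
#' @return A list of class `eqn_observer`.
#' @examples
#' observer_params(sigma_int = 4.5, efficiency = 0.8)
#' @export
observer_params <- function(sigma_int, efficiency = 1, lapse = 0) {
  stopifnot(
    sigma_int >= 0,
    efficiency > 0, efficiency <= 1,
    lapse >= 0, lapse <= 0.05
  )
  structure(
    list(sigma_int = sigma_int, efficiency = efficiency, lapse = lapse),
    class = "eqn_observer"
  )
}

#' @export
print.eqn_observer <- function(x, ...) {
  cat(sprintf(
    "<eqn_observer> sigma_int = %.3g deg, efficiency = %.3g, lapse = %.3g\n",
    x$sigma_int, x$efficiency, x$lapse
  ))
  invisible(x)
}

#' One 4AFC decision of the simulated observer
#'
#' Given the four stimuli of a trial (exactly one valid), the observer adds
#' internal orientation noise to every element's jittered orientation and,
#' for each quadrant, scores a randomly drawn subset of elements by
#' template matching on the doubled-angle circle:
#' `sum(cos(2 * (perceived - valid_template)) - cos(2 * (perceived -
#' distractor_template)))`. The quadrant with the highest score is chosen;
#' with probability `lapse` the response is uniform over quadrants, and
#' exact ties are broken uniformly at random.
#'
#' @param stimuli List of four [make_stimulus()] objects sharing amplitude
#'   and noise level, exactly one with `is_valid = TRUE`.
#' @param params An [observer_params()].
#' @return Integer index (1-4) of the chosen stimulus.
#' @examples
#' set.seed(1)
#' trial <- make_trial_stimuli(0.2, noise_sd = 0)
#' decide_4afc(trial, observer_params(sigma_int = 0))
#' @export
decide_4afc <- function(stimuli, params) {
  stopifnot(length(stimuli) == 4)
  valid <- vapply(stimuli, function(s) s$is_valid, logical(1))
  if (sum(valid) != 1) stop("exactly one of the four stimuli must be valid")
  amps <- vapply(stimuli, function(s) s$amplitude, numeric(1))
  sds <- vapply(stimuli, function(s) s$noise_sd, numeric(1))
  if (length(unique(amps)) != 1 || length(unique(sds)) != 1) {
    stop("all four stimuli must share amplitude and noise level")
  }
  n <- length(stimuli[[1]]$base_orientations)
  k <- ceiling(params$efficiency * n)
  scores <- vapply(stimuli, function(s) {
    perceived <- s$jittered_orientations + stats::rnorm(n, 0, params$sigma_int)
    idx <- if (k < n) sample.int(n, k) else seq_len(n)
    dv <- deg2(perceived[idx] - s$valid_orientations[idx])
    dd <- deg2(perceived[idx] - s$distractor_orientations[idx])
    sum(cos(dv) - cos(dd))
  }, numeric(1))
  if (params$lapse > 0 && stats::runif(1) < params$lapse) {
    return(sample.int(4, 1))
  }
  top <- which(scores >= max(scores) - 1e-12)
  if (length(top) > 1) top[sample.int(length(top), 1)] else top
}

# degrees of orientation -> doubled angle in radians
deg2 <- function(theta) theta * (pi / 90)

#' Build the four stimuli of one trial
#'
#' Places the valid contour in a (given or random) quadrant and
#' opposite-curvature distractors in the other three. Each quadrant gets
#' an independent random chord orientation and curvature sign.
#'
#' @inheritParams make_stimulus
#' @param target_quadrant Quadrant code for the target, or `NULL` to draw
#'   uniformly at random.
#' @return List of four `eqn_stimulus` objects in quadrant order
#'   `UL, UR, LL, LR`.
#' @export
make_trial_stimuli <- function(amplitude, noise_sd, config = task_config(),
                               target_quadrant = NULL) {
  quads <- quadrant_levels()
  if (is.null(target_quadrant)) {
    target_quadrant <- quads[sample.int(4, 1)]
  } else {
    target_quadrant <- match.arg(target_quadrant, quads)
  }
  purrr::map(quads, function(q) {
    make_stimulus(
      amplitude,
      is_valid = identical(q, target_quadrant),
      noise_sd = noise_sd,
      quadrant = q,
      config = config,
      chord_orientation = stats::runif(1, 0, 180),
      curvature_sign = sample(c(-1, 1), 1)
    )
  })
}

# Signed tangent deviations from the chord, degrees, for one amplitude.
tangent_deviation <- function(amplitude, config) {
  n <- config$n_wavelets
  if (amplitude == 0) return(rep(0, n))
  L <- config$chord_length
  R <- amplitude / 2 + L^2 / (8 * amplitude)
  half <- asin(L / (2 * R))
  -seq(-half, half, length.out = n) * 180 / pi
}

# Fast per-trial simulation used by the cohort generator and staircases.
# Equivalent to building four stimuli and calling decide_4afc(), but works
# directly on tangent deviations (the chord orientation cancels out of the
# template-matching score). Returns TRUE for a correct response.
simulate_trial_correct <- function(amplitude, noise_sd, params,
                                   config = task_config()) {
  n <- config$n_wavelets
  trial_core(
    dev2 = 2 * deg2(tangent_deviation(amplitude, config)),
    sig_rad = sqrt(noise_sd^2 + params$sigma_int^2) * (pi / 90),
    k = ceiling(params$efficiency * n),
    n = n,
    lapse = params$lapse
  )
}

# Innermost trial kernel: dev2 = doubled tangent deviations (radians of
# doubled angle), sig_rad = total orientation noise on the same scale.
trial_core <- function(dev2, sig_rad, k, n, lapse) {
  target <- sample.int(4L, 1L)
  if (lapse > 0 && stats::runif(1) < lapse) {
    return(sample.int(4L, 1L) == target)
  }
  eps <- matrix(stats::rnorm(4L * n, 0, sig_rad), n, 4L)
  signs <- c(-1, 1)[(stats::runif(4) < 0.5) + 1L]
  d2 <- dev2 %o% signs
  # distractor score for all quadrants, target column overridden
  m <- cos(eps - d2) - cos(eps)
  tc <- eps[, target]
  m[, target] <- cos(tc) - cos(tc + d2[, target])
  if (k < n) {
    scores <- numeric(4L)
    for (q in 1:4) scores[q] <- sum(m[sample.int(n, k), q])
  } else {
    scores <- colSums(m)
  }
  top <- which(scores >= max(scores) - 1e-12)
  choice <- if (length(top) > 1L) top[sample.int(length(top), 1L)] else top
  choice == target
}

# Staircase responder with per-amplitude geometry caching.
observer_responder <- function(params, noise_sd, config) {
  n <- config$n_wavelets
  k <- ceiling(params$efficiency * n)
  sig_rad <- sqrt(noise_sd^2 + params$sigma_int^2) * (pi / 90)
  lapse <- params$lapse
  cache <- new.env(parent = emptyenv())
  function(a) {
    key <- as.character(a)
    dev2 <- cache[[key]]
    if (is.null(dev2)) {
      dev2 <- 2 * deg2(tangent_deviation(a, config))
      cache[[key]] <- dev2
    }
    trial_core(dev2, sig_rad, k, n, lapse)
  }
}

#' Empirical psychometric function of the simulated observer
#'
#' Monte-Carlo proportion correct of the 4AFC observer on an amplitude
#' grid at one external-noise level.
#'
#' @param params An [observer_params()].
#' @param noise_sd External orientation-noise SD, degrees.
#' @param amplitudes Numeric vector of curvature amplitudes, degrees.
#' @param n_per_point Trials per amplitude (>= 1).
#' @param config A [task_config()].
#' @param full_stimuli If `TRUE`, simulate through [make_trial_stimuli()]
#'   and [decide_4afc()]; the default uses an equivalent fast path that
#'   skips stimulus construction.
#' @return A tibble with columns `amplitude`, `noise_sd`, `n_trials`,
#'   `n_correct`, `prop_correct`.
#' @examples
#' set.seed(2)
#' observer_psychometric(observer_params(4), 0, c(0.02, 0.1, 0.3), 100)
#' @export
observer_psychometric <- function(params, noise_sd, amplitudes,
                                  n_per_point = 100,
                                  config = task_config(),
                                  full_stimuli = FALSE) {
  stopifnot(n_per_point >= 1)
  nc <- vapply(amplitudes, function(a) {
    if (full_stimuli) {
      sum(vapply(seq_len(n_per_point), function(i) {
        stims <- make_trial_stimuli(a, noise_sd, config)
        which(vapply(stims, `[[`, logical(1), "is_valid")) ==
          decide_4afc(stims, params)
      }, logical(1)))
    } else {
      sum(vapply(seq_len(n_per_point), function(i) {
        simulate_trial_correct(a, noise_sd, params, config)
      }, logical(1)))
    }
  }, numeric(1))
  tibble::tibble(
    amplitude = amplitudes,
    noise_sd = noise_sd,
    n_trials = as.integer(n_per_point),
    n_correct = as.integer(nc),
    prop_correct = nc / n_per_point
  )
}
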