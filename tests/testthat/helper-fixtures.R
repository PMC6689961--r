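# Shared builders for the test suite. Everything is generated in code;
# no fixture files.

# A small, fast cohort spec: two groups at the default internal-noise
# locations but few subjects.
tiny_cohort <- function(n1 = 3L, n2 = 3L, seed = 1L, ...) {
  g <- default_groups()
  g$n_subjects <- c(n1, n2)
  cohort_spec(groups = g, seed = seed, ...)
}

# Fast staircase used where convergence quality is not under test.
fast_staircase <- function(max_trials = 25) staircase_config(max_trials = max_trials)

# Bernoulli responder driven by a fixed Gumbel psychometric function.
gumbel_responder <- function(alpha, slope, lambda = 0) {
  function(a) stats::runif(1) < gumbel_probability(log10(a), alpha, slope,
                                                   0.25, lambda)
}

# Binomial data simulated from a known Gumbel psychometric function.
simulate_binned <- function(alpha, slope, lambda = 0, amplitudes, n_per_point) {
  x <- log10(amplitudes)
  p <- gumbel_probability(x, alpha, slope, 0.25, lambda)
  tibble::tibble(
    amplitude = amplitudes,
    n_trials = as.integer(n_per_point),
    n_correct = stats::rbinom(length(p), n_per_point, p)
  )
}

# Long factorial dataset: n1 + n2 subjects x 4 quadrants, lognormal
# responses with a subject random effect and an optional group shift.
factorial_data <- function(n1, n2, shift = 0, quadrant_shift = NULL) {
  n <- n1 + n2
  subj <- rep(seq_len(n), each = 4)
  grp <- rep(c(rep("a", n1), rep("b", n2)), each = 4)
  base <- rep(stats::rnorm(n), each = 4)
  y <- exp(0.5 * (base + stats::rnorm(4 * n))) + shift * (grp == "b")
  if (!is.null(quadrant_shift)) y <- y + rep(quadrant_shift, n)
  tibble::tibble(
    subject = subj, group = grp,
    quadrant = rep(quadrant_levels(), n), y = y
  )
}
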