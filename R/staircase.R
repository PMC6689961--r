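#' Run a 2-down-1-up adaptive staircase
#'
#' Tracks curvature amplitude with the transformed up-down rule: after two
#' consecutive correct responses the amplitude is divided by the current
#' step factor, after every error it is multiplied by it. The
#' consecutive-correct counter resets whenever the amplitude changes. A
#' reversal is a change in the direction of movement; after
#' `reversals_to_shrink` reversals the step factor shrinks from its
#' initial to its final value. The run terminates at the earlier of
#' `max_trials` trials and `max_reversals` reversals, and the converged
#' amplitude is the geometric mean of the reversal amplitudes recorded
#' after the step shrink (falling back to all reversal amplitudes, then to
#' the final amplitude, when a run ends before enough reversals occur).
#' This rule converges where P(correct) = sqrt(1/2) ~ 70.7%.
#'
#' @param responder Function of one argument (amplitude, degrees) returning
#'   `TRUE` for a correct response.
#' @param config A [staircase_config()].
#' @return An object of class `eqn_staircase`: list with `trials` (tibble
#'   of `trial`, `amplitude`, `correct`), `reversal_trials`,
#'   `reversal_amplitudes`, `converged_amplitude`, `n_reversals`,
#'   `clipped` (count of bound clips), and `config`.
#' @examples
#' set.seed(1)
#' obs <- observer_params(sigma_int = 4, efficiency = 1)
#' run <- run_staircase(function(a) simulate_trial(a, 0, obs), staircase_config())
#' run$converged_amplitude
#' @export
run_staircase <- function(responder, config = staircase_config()) {
  lo <- config$amplitude_bounds[1]
  hi <- config$amplitude_bounds[2]
  amp <- config$start_amplitude
  step <- config$step_factor_initial
  n_correct_row <- 0L
  last_dir <- 0L # -1 down, +1 up, 0 none yet
  n_rev <- 0L
  amps <- numeric(config$max_trials)
  corr <- logical(config$max_trials)
  rev_trial <- integer(0)
  rev_amp <- numeric(0)
  rev_post_shrink <- logical(0)
  clipped <- 0L
  t <- 0L
  while (t < config$max_trials && n_rev < config$max_reversals) {
    t <- t + 1L
    ok <- isTRUE(responder(amp))
    amps[t] <- amp
    corr[t] <- ok
    dir <- 0L
    if (ok) {
      n_correct_row <- n_correct_row + 1L
      if (n_correct_row == 2L) {
        dir <- -1L
        n_correct_row <- 0L
      }
    } else {
      dir <- 1L
      n_correct_row <- 0L
    }
    if (dir != 0L) {
      if (last_dir != 0L && dir != last_dir) {
        n_rev <- n_rev + 1L
        rev_trial <- c(rev_trial, t)
        rev_amp <- c(rev_amp, amp)
        rev_post_shrink <- c(rev_post_shrink,
                             n_rev > config$reversals_to_shrink)
        if (n_rev == config$reversals_to_shrink) {
          step <- config$step_factor_final
        }
      }
      last_dir <- dir
      new_amp <- if (dir < 0L) amp / step else amp * step
      if (new_amp < lo || new_amp > hi) clipped <- clipped + 1L
      amp <- min(max(new_amp, lo), hi)
    }
  }
  used <- rev_amp[rev_post_shrink]
  converged <- if (length(used) >= 1) {
    exp(mean(log(used)))
  } else if (length(rev_amp) >= 1) {
    exp(mean(log(rev_amp)))
  } else {
    amp
  }
  structure(
    list(
      trials = tibble::tibble(
        trial = seq_len(t),
        amplitude = amps[seq_len(t)],
        correct = corr[seq_len(t)]
      ),
      reversal_trials = rev_trial,
      reversal_amplitudes = rev_amp,
      converged_amplitude = converged,
      n_reversals = n_rev,
      clipped = clipped,
      config = config
    ),
    class = "eqn_staircase"
  )
}

#' @export
print.eqn_staircase <- function(x, ...) {
  cat(sprintf(
    "<eqn_staircase> %d trials, %d reversals, converged at %.4g deg\n",
    nrow(x$trials), x$n_reversals, x$converged_amplitude
  ))
  invisible(x)
}

#' Simulate one 4AFC trial for a given observer
#'
#' Convenience responder for [run_staircase()]: simulates a single trial
#' of the good-continuation task at the given amplitude and external-noise
#' level and returns whether the simulated observer chose the target.
#'
#' @param amplitude Curvature amplitude, degrees.
#' @param noise_sd External orientation-noise SD, degrees.
#' @param params An [observer_params()].
#' @param config A [task_config()].
#' @param full_stimuli If `TRUE`, go through full stimulus construction and
#'   [decide_4afc()]; default uses the equivalent fast path.
#' @return Logical, `TRUE` if the response was correct.
#' @export
simulate_trial <- function(amplitude, noise_sd, params,
                           config = task_config(), full_stimuli = FALSE) {
  if (full_stimuli) {
    stims <- make_trial_stimuli(amplitude, noise_sd, config)
    target <- which(vapply(stims, `[[`, logical(1), "is_valid"))
    decide_4afc(stims, params) == target
  } else {
    simulate_trial_correct(amplitude, noise_sd, params, config)
  }
}

#' @export
autoplot.eqn_staircase <- function(object, ...) {
  df <- object$trials
  rev_df <- df[df$trial %in% object$reversal_trials, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial, y = .data$amplitude)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$correct)) +
    ggplot2::geom_point(data = rev_df, colour = "red", size = 2) +
    ggplot2::geom_hline(yintercept = object$converged_amplitude,
                        linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Trial", y = "Amplitude (deg, log scale)",
                  shape = "Correct")
}
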