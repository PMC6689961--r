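#' Task configuration for the good-continuation experiment
#'
#' Bundles the stimulus and display parameters of the four-alternative
#' forced-choice (4AFC) contour task: each trial shows four contours, one
#' per visual-field quadrant, each made of `n_wavelets` log-Gabor elements
#' resting on an invisible curved path. The defaults reproduce the task as
#' run psychophysically: seven wavelets at 6 cycles/deg peak spatial
#' frequency (1.6 octave bandwidth, +/-25 deg orientation bandwidth),
#' envelope FWHM of 1.17 cycles along and 0.91 cycles across the stripes,
#' contours centred 2.8 deg from fixation, 400 ms presentations, and
#' external orientation noise at 0, 8 and 16 deg SD.
#'
#' The path geometry is a circular arc: `chord_length` fixes the distance
#' between the contour endpoints and the curvature amplitude is the arc's
#' sagitta (see [contour_path()]).
#'
#' @param n_wavelets Number of elements per contour (>= 3).
#' @param peak_sf Peak spatial frequency, cycles per degree.
#' @param sf_bandwidth Spatial-frequency bandwidth, octaves.
#' @param ori_bandwidth Orientation half-bandwidth, degrees.
#' @param fwhm_along,fwhm_across Envelope full width at half magnitude,
#'   in carrier cycles, along and across the stripes.
#' @param eccentricity Contour-centre eccentricity, degrees of visual angle.
#' @param stim_duration Presentation duration, ms.
#' @param noise_levels External orientation-noise SDs in degrees; must be
#'   strictly increasing with first element 0.
#' @param chord_length Chord of the contour path, degrees of visual angle.
#' @param pixels_per_deg Pixels per degree, used only by [render_stimulus()].
#' @return A list of class `eqn_task_config`.
#' @examples
#' cfg <- task_config()
#' cfg$noise_levels
#' @export
task_config <- function(n_wavelets = 7,
                        peak_sf = 6,
                        sf_bandwidth = 1.6,
                        ori_bandwidth = 25,
                        fwhm_along = 1.17,
                        fwhm_across = 0.91,
                        eccentricity = 2.8,
                        stim_duration = 400,
                        noise_levels = c(0, 8, 16),
                        chord_length = 1.4,
                        pixels_per_deg = 96) {
  stopifnot(
    n_wavelets >= 3,
    length(noise_levels) >= 1,
    noise_levels[1] == 0,
    !is.unsorted(noise_levels, strictly = TRUE),
    peak_sf > 0, sf_bandwidth > 0, ori_bandwidth > 0,
    fwhm_along > 0, fwhm_across > 0, eccentricity > 0,
    stim_duration > 0, chord_length > 0, pixels_per_deg > 0
  )
  structure(
    list(
      n_wavelets = as.integer(n_wavelets),
      peak_sf = peak_sf,
      sf_bandwidth = sf_bandwidth,
      ori_bandwidth = ori_bandwidth,
      fwhm_along = fwhm_along,
      fwhm_across = fwhm_across,
      eccentricity = eccentricity,
      stim_duration = stim_duration,
      noise_levels = as.numeric(noise_levels),
      chord_length = chord_length,
      pixels_per_deg = pixels_per_deg
    ),
    class = "eqn_task_config"
  )
}

#' Staircase configuration
#'
#' Parameters of the performance-dependent 2-down-1-up amplitude staircase:
#' amplitude is divided by the current step factor after every two
#' consecutive correct responses and multiplied by it after every error, so
#' the track converges where P(correct) = sqrt(1/2) ~ 70.7% (printed as
#' 70%). A run terminates after `max_trials` trials or `max_reversals`
#' reversals, whichever comes first. Steps are multiplicative and shrink
#' from `step_factor_initial` to `step_factor_final` after
#' `reversals_to_shrink` reversals; the converged amplitude is the
#' geometric mean of the post-shrink reversal amplitudes.
#'
#' @param start_amplitude Starting amplitude in degrees (sagitta); defaults
#'   to half the upper amplitude bound, clearly suprathreshold.
#' @param step_factor_initial,step_factor_final Multiplicative step factors
#'   (> 1); defaults 10^0.1 and 10^0.05.
#' @param reversals_to_shrink Reversal count after which the step shrinks.
#' @param max_trials Trial cap per run (40).
#' @param max_reversals Reversal cap per run (12).
#' @param amplitude_bounds Two-element numeric, amplitude clipping range in
#'   degrees.
#' @return A list of class `eqn_staircase_config`.
#' @examples
#' staircase_config()$max_trials
#' @export
staircase_config <- function(start_amplitude = NULL,
                             step_factor_initial = 10^0.1,
                             step_factor_final = 10^0.05,
                             reversals_to_shrink = 3,
                             max_trials = 40,
                             max_reversals = 12,
                             amplitude_bounds = c(0.002, 0.3)) {
  stopifnot(
    step_factor_initial > 1, step_factor_final > 1,
    max_trials >= 1, max_reversals >= 1,
    length(amplitude_bounds) == 2,
    amplitude_bounds[1] > 0,
    amplitude_bounds[1] < amplitude_bounds[2]
  )
  if (is.null(start_amplitude)) start_amplitude <- amplitude_bounds[2] / 2
  stopifnot(
    start_amplitude >= amplitude_bounds[1],
    start_amplitude <= amplitude_bounds[2]
  )
  structure(
    list(
      start_amplitude = start_amplitude,
      step_factor_initial = step_factor_initial,
      step_factor_final = step_factor_final,
      reversals_to_shrink = as.integer(reversals_to_shrink),
      max_trials = as.integer(max_trials),
      max_reversals = as.integer(max_reversals),
      amplitude_bounds = as.numeric(amplitude_bounds)
    ),
    class = "eqn_staircase_config"
  )
}

#' Quadrant codes
#'
#' The four visual-field quadrants, coded `UL`, `UR`, `LL`, `LR`
#' (upper/lower x left/right, from the subject's point of view). This
#' ordering is used consistently in trial tables and contrast matrices.
#'
#' @return Character vector of the four quadrant codes.
#' @export
quadrant_levels <- function() c("UL", "UR", "LL", "LR")

#' Read a task / staircase / cohort configuration from YAML
#'
#' Reads a YAML file with optional top-level blocks `task`, `staircase` and
#' `cohort`, merges them over the package defaults, and returns validated
#' configuration objects.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `task` ([task_config()]),
#'   `staircase` ([staircase_config()]) and, when a `cohort` block is
#'   present, `cohort` ([cohort_spec()]).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  task <- do.call(task_config, raw$task %||% list())
  stair <- do.call(staircase_config, raw$staircase %||% list())
  out <- list(task = task, staircase = stair)
  if (!is.null(raw$cohort)) {
    args <- raw$cohort
    if (!is.null(args$groups)) {
      args$groups <- purrr::map(args$groups, tibble::as_tibble)
      args$groups <- dplyr::bind_rows(args$groups)
    }
    out$cohort <- do.call(cohort_spec, args)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
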