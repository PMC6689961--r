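#' Default group structure for synthetic cohorts
#'
#' Group internal-noise locations follow the reported group pseudo-medians
#' (controls 4.51 deg, single-concussion 6.1 deg, multiple-concussion
#' 6.69 deg) with the reported post-exclusion sample sizes (21 / 50 / 5).
#' Efficiency distributions are identical across groups: elevated internal
#' noise with preserved integration efficiency is the structure the
#' generator emulates. Subject heterogeneity is log-normal with a 0.25
#' log-unit scale (positive, right-skewed).
#'
#' @param three_groups Include the small multiple-concussion group?
#' @return Tibble with one row per group: `name`, `n_subjects`,
#'   `sigma_int_location`, `sigma_int_scale`, `efficiency_location`,
#'   `efficiency_scale`.
#' @export
default_groups <- function(three_groups = FALSE) {
  g <- tibble::tibble(
    name = c("control", "mtbi", "multiple_tbi"),
    n_subjects = c(21L, 50L, 5L),
    sigma_int_location = c(4.51, 6.1, 6.69),
    sigma_int_scale = 0.25,
    efficiency_location = 0.7,
    efficiency_scale = 0.25
  )
  if (three_groups) g else g[1:2, ]
}

#' Specification of a synthetic cohort
#'
#' Defines the subject population the generator draws from: per-group
#' log-normal distributions of internal noise and efficiency, optional
#' per-quadrant multiplicative offsets (e.g. a right-hemifield advantage),
#' and the lapse-rate range. Together with a [task_config()] and
#' [staircase_config()] this fully determines the simulated experiment.
#'
#' @param groups Tibble as returned by [default_groups()].
#' @param quadrant_effects Optional tibble with columns `group`,
#'   `quadrant`, `sigma_int_offset`, `efficiency_offset` (multiplicative,
#'   default 1 everywhere).
#' @param lapse_range Length-2 numeric within \[0, 0.05\]; each subject's
#'   lapse rate is uniform in this range.
#' @param seed Integer seed making the cohort fully reproducible.
#' @return A list of class `eqn_cohort_spec`.
#' @examples
#' cohort_spec(seed = 7)
#' @export
cohort_spec <- function(groups = default_groups(),
                        quadrant_effects = NULL,
                        lapse_range = c(0, 0.02),
                        seed = 1L) {
  groups <- tibble::as_tibble(groups)
  needed <- c("name", "n_subjects", "sigma_int_location", "sigma_int_scale",
              "efficiency_location", "efficiency_scale")
  stopifnot(
    all(needed %in% names(groups)),
    all(groups$n_subjects >= 1),
    all(groups$sigma_int_location > 0),
    all(groups$sigma_int_scale >= 0),
    all(groups$efficiency_location > 0),
    all(groups$efficiency_scale >= 0),
    length(lapse_range) == 2,
    lapse_range[1] >= 0, lapse_range[2] <= 0.05,
    lapse_range[1] <= lapse_range[2]
  )
  if (!is.null(quadrant_effects)) {
    quadrant_effects <- tibble::as_tibble(quadrant_effects)
    stopifnot(all(c("group", "quadrant", "sigma_int_offset",
                    "efficiency_offset") %in% names(quadrant_effects)))
  }
  structure(
    list(
      groups = groups,
      quadrant_effects = quadrant_effects,
      lapse_range = as.numeric(lapse_range),
      seed = as.integer(seed)
    ),
    class = "eqn_cohort_spec"
  )
}

#' @export
print.eqn_cohort_spec <- function(x, ...) {
  cat("<eqn_cohort_spec>\n")
  print(x$groups)
  cat(sprintf("lapse in [%g, %g], seed %d\n",
              x$lapse_range[1], x$lapse_range[2], x$seed))
  invisible(x)
}

quadrant_offset <- function(spec, group_name, quad, column) {
  qe <- spec$quadrant_effects
  if (is.null(qe)) return(1)
  row <- qe[qe$group == group_name & qe$quadrant == quad, ]
  if (nrow(row) == 0) 1 else row[[column]][1]
}

#' Draw one subject's per-quadrant observer parameters
#'
#' Internal noise and efficiency are drawn log-normally around the group
#' location times the quadrant offset (the location is the log-normal
#' median); efficiency is capped at 1 and the lapse rate is uniform in
#' the spec's range (one value per subject). Uses the current RNG state.
#'
#' @param spec A [cohort_spec()].
#' @param group_name Name of the group to draw from.
#' @return Tibble with one row per quadrant: `quadrant`, `sigma_int`,
#'   `efficiency`, `lapse`.
#' @export
sample_subject <- function(spec, group_name) {
  g <- spec$groups[spec$groups$name == group_name, ]
  if (nrow(g) != 1) stop("unknown group: ", group_name)
  lapse <- stats::runif(1, spec$lapse_range[1], spec$lapse_range[2])
  purrr::map_dfr(quadrant_levels(), function(q) {
    s_off <- quadrant_offset(spec, group_name, q, "sigma_int_offset")
    e_off <- quadrant_offset(spec, group_name, q, "efficiency_offset")
    tibble::tibble(
      quadrant = q,
      sigma_int = g$sigma_int_location * s_off *
        exp(stats::rnorm(1, 0, g$sigma_int_scale)),
      efficiency = min(1, g$efficiency_location * e_off *
                         exp(stats::rnorm(1, 0, g$efficiency_scale))),
      lapse = lapse
    )
  })
}

#' Generate a complete synthetic trial table
#'
#' Simulates the full experiment for every subject in the cohort: for each
#' of the three external-noise blocks (block order randomized per subject)
#' and each visual-field quadrant, an independent 2-down-1-up staircase is
#' run against the subject's simulated observer, and every trial is
#' recorded. The result is a long trial table ready for
#' [fit_thresholds()].
#'
#' @param spec A [cohort_spec()].
#' @param task A [task_config()].
#' @param staircase A [staircase_config()].
#' @param sessions Number of staircase repeats per subject x block x
#'   quadrant (default 1).
#' @return Tibble with columns `subject_id`, `group`, `block_order_index`,
#'   `noise_sd`, `quadrant`, `session`, `trial_index`, `amplitude`,
#'   `correct`, `seed_trace`. The subjects' generating parameters are
#'   attached as attribute `"subjects"` (see [cohort_subjects()]).
#' @examples
#' spec <- cohort_spec(groups = default_groups()[1, ], seed = 1)
#' spec$groups$n_subjects <- 1L
#' trials <- generate_cohort(spec)
#' nrow(trials) <= 3 * 4 * 40
#' @export
generate_cohort <- function(spec, task = task_config(),
                            staircase = staircase_config(), sessions = 1) {
  set.seed(spec$seed)
  subjects <- list()
  rows <- list()
  for (gi in seq_len(nrow(spec$groups))) {
    gname <- spec$groups$name[gi]
    for (si in seq_len(spec$groups$n_subjects[gi])) {
      sid <- sprintf("%s_%02d", gname, si)
      pars <- sample_subject(spec, gname)
      pars$subject_id <- sid
      pars$group <- gname
      subjects[[length(subjects) + 1]] <- pars
      block_order <- sample(task$noise_levels)
      for (bi in seq_along(block_order)) {
        nsd <- block_order[bi]
        for (q in quadrant_levels()) {
          obs <- observer_params(
            sigma_int = pars$sigma_int[pars$quadrant == q],
            efficiency = pars$efficiency[pars$quadrant == q],
            lapse = pars$lapse[1]
          )
          responder <- observer_responder(obs, nsd, task)
          for (sess in seq_len(sessions)) {
            run <- run_staircase(responder, staircase)
            tr <- run$trials
            rows[[length(rows) + 1]] <- tibble::tibble(
              subject_id = sid,
              group = gname,
              block_order_index = bi,
              noise_sd = nsd,
              quadrant = q,
              session = sess,
              trial_index = tr$trial,
              amplitude = tr$amplitude,
              correct = tr$correct,
              seed_trace = sprintf("%d/%s/b%d/%s/s%d",
                                   spec$seed, sid, bi, q, sess)
            )
          }
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "subjects") <- dplyr::bind_rows(subjects)
  out
}

#' Generating parameters of a synthetic cohort
#'
#' @param trials A trial table from [generate_cohort()].
#' @return Tibble with one row per subject x quadrant: `subject_id`,
#'   `group`, `quadrant`, `sigma_int`, `efficiency`, `lapse`.
#' @export
cohort_subjects <- function(trials) {
  s <- attr(trials, "subjects")
  if (is.null(s)) stop("trial table carries no generating parameters")
  s[, c("subject_id", "group", "quadrant", "sigma_int", "efficiency", "lapse")]
}

#' Threshold-versus-noise curve of one simulated observer
#'
#' Measures the observer's threshold at each external-noise level by
#' running repeated staircases and taking the geometric mean of the
#' converged amplitudes. Used for calibration and for checking that the
#' simulated observer obeys the Linear Amplifier Model.
#'
#' @param params An [observer_params()].
#' @param noise_levels External-noise SDs, degrees.
#' @param n_staircases Staircase repeats per level.
#' @param task,staircase Configurations.
#' @return Tibble with `noise_sd`, `threshold`, `n_staircases`.
#' @export
simulate_tvn <- function(params, noise_levels = c(0, 8, 16),
                         n_staircases = 8, task = task_config(),
                         staircase = staircase_config()) {
  purrr::map_dfr(noise_levels, function(nsd) {
    responder <- observer_responder(params, nsd, task)
    conv <- vapply(seq_len(n_staircases), function(i) {
      run_staircase(responder, staircase)$converged_amplitude
    }, numeric(1))
    tibble::tibble(
      noise_sd = nsd,
      threshold = exp(mean(log(conv))),
      n_staircases = as.integer(n_staircases)
    )
  })
}

#' Calibrate the efficiency-fraction to LAM-beta mapping
#'
#' The simulated observer expresses efficiency as the fraction of elements
#' pooled, while the Linear Amplifier Model expresses it as `beta`. This
#' runs forward simulations over a grid of efficiency fractions and
#' returns the fitted `beta` for each, so cohort specifications can be
#' stated in either unit. The mapping is monotone increasing.
#'
#' @param efficiencies Grid of pooling fractions in (0, 1].
#' @param sigma_int Internal noise used during calibration, degrees.
#' @param n_staircases Staircase repeats per noise level.
#' @param task,staircase Configurations.
#' @return Tibble with `efficiency`, `beta`, `sigma_int_fitted`.
#' @export
calibrate_efficiency_beta <- function(efficiencies = seq(0.2, 1, by = 0.2),
                                      sigma_int = 5, n_staircases = 12,
                                      task = task_config(),
                                      staircase = staircase_config()) {
  purrr::map_dfr(efficiencies, function(eff) {
    tvn <- simulate_tvn(observer_params(sigma_int, eff),
                        task$noise_levels, n_staircases, task, staircase)
    fit <- fit_lam(tvn$noise_sd, tvn$threshold)
    tibble::tibble(
      efficiency = eff,
      beta = fit$beta,
      sigma_int_fitted = fit$sigma_internal
    )
  })
}
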