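#' Validate a trial table
#'
#' Checks the trial-record schema produced by [generate_cohort()]:
#' required columns, positive amplitudes, noise levels drawn from the task
#' configuration, and uniqueness of (subject, block, quadrant, session,
#' trial) keys. Errors name the first offending row.
#'
#' @param trials Data frame of trial records.
#' @param task A [task_config()] supplying the legal noise levels.
#' @return `trials` as a tibble, invisibly usable downstream.
#' @export
validate_trials <- function(trials, task = task_config()) {
  trials <- tibble::as_tibble(trials)
  needed <- c("subject_id", "group", "noise_sd", "quadrant",
              "trial_index", "amplitude", "correct")
  missing <- setdiff(needed, names(trials))
  if (length(missing)) {
    stop("trial table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!"session" %in% names(trials)) trials$session <- 1L
  bad <- which(!(trials$amplitude > 0))
  if (length(bad)) stop("non-positive amplitude at row ", bad[1])
  bad <- which(!trials$noise_sd %in% task$noise_levels)
  if (length(bad)) stop("unknown noise level at row ", bad[1])
  bad <- which(!trials$quadrant %in% quadrant_levels())
  if (length(bad)) stop("unknown quadrant code at row ", bad[1])
  key <- paste(trials$subject_id, trials$noise_sd, trials$quadrant,
               trials$session, trials$trial_index)
  dup <- which(duplicated(key))
  if (length(dup)) stop("duplicate trial key at row ", dup[1])
  trials
}

#' Write / read trial tables as CSV
#'
#' Plain UTF-8 CSV with a header and "." decimal separator; read is
#' validated against the schema so that write-then-read round-trips.
#'
#' @param trials Trial table.
#' @param path File path.
#' @param task A [task_config()] for validation on read.
#' @return `write_trials()` returns `path` invisibly; `read_trials()`
#'   returns a validated tibble.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path, task = task_config()) {
  validate_trials(utils::read.csv(path, stringsAsFactors = FALSE), task)
}

#' Fit psychometric functions to every design cell
#'
#' Bins trials and fits the Gumbel psychometric function (guess rate
#' 0.25, lapse in \[0, 0.05\]) per subject x quadrant x noise level,
#' applying the chi-square screen for unreliable high-amplitude points.
#' Cells with fewer than 3 distinct amplitudes are skipped with a warning.
#'
#' @param trials Validated trial table.
#' @param prune Apply [prune_top_points()]? Default `TRUE`.
#' @param task A [task_config()].
#' @return Tibble with one row per fitted cell: design labels, `threshold`
#'   (`10^alpha`, degrees), `alpha`, `slope`, `lambda`, `deviance`,
#'   `gof_p`, `n_points`, `n_trials`, `n_removed`, `at_boundary`.
#' @export
fit_thresholds <- function(trials, prune = TRUE, task = task_config()) {
  trials <- validate_trials(trials, task)
  cells <- dplyr::group_split(
    dplyr::group_by(trials, .data$subject_id, .data$group,
                    .data$quadrant, .data$noise_sd)
  )
  skipped <- 0L
  rows <- purrr::map(cells, function(cell) {
    binned <- bin_trials(cell$amplitude, cell$correct)
    if (nrow(binned) < 3) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    fit <- if (prune) prune_top_points(binned) else fit_gumbel(binned)
    tibble::tibble(
      subject_id = cell$subject_id[1],
      group = cell$group[1],
      quadrant = cell$quadrant[1],
      noise_sd = cell$noise_sd[1],
      threshold = fit$threshold_amplitude,
      alpha = fit$alpha,
      slope = fit$slope,
      lambda = fit$lambda,
      deviance = fit$deviance,
      gof_p = fit$gof_p,
      n_points = nrow(fit$data),
      n_trials = sum(fit$data$n_trials),
      n_removed = length(fit$removed_points),
      at_boundary = fit$at_boundary
    )
  })
  if (skipped > 0) {
    warning(skipped, " cell(s) skipped: fewer than 3 distinct amplitudes")
  }
  dplyr::bind_rows(rows)
}

#' Fit the Linear Amplifier Model per subject and quadrant
#'
#' Takes the per-cell threshold table from [fit_thresholds()] and fits the
#' LAM across the external-noise levels of every subject x quadrant,
#' yielding the internal-noise and efficiency estimates that feed the
#' group analysis. Cells missing a noise level are skipped with a warning.
#'
#' @param thresholds Output of [fit_thresholds()].
#' @param noise_levels The external-noise levels every fit must cover.
#' @return Tibble with one row per subject x quadrant: `subject_id`,
#'   `group`, `quadrant`, `sigma_int`, `beta`, `rss_log`, `at_boundary`.
#' @export
fit_lam_table <- function(thresholds, noise_levels = c(0, 8, 16)) {
  cells <- dplyr::group_split(
    dplyr::group_by(thresholds, .data$subject_id, .data$group, .data$quadrant)
  )
  skipped <- 0L
  rows <- purrr::map(cells, function(cell) {
    if (!all(noise_levels %in% cell$noise_sd)) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    cell <- cell[match(noise_levels, cell$noise_sd), ]
    fit <- fit_lam(cell$noise_sd, cell$threshold)
    tibble::tibble(
      subject_id = cell$subject_id[1],
      group = cell$group[1],
      quadrant = cell$quadrant[1],
      sigma_int = fit$sigma_internal,
      beta = fit$beta,
      rss_log = fit$rss_log,
      at_boundary = fit$at_boundary
    )
  })
  if (skipped > 0) {
    warning(skipped, " subject x quadrant cell(s) lacked a complete ",
            "threshold-versus-noise triple and were skipped")
  }
  dplyr::bind_rows(rows)
}

#' Flag outlier subjects on their LAM parameters
#'
#' Within each group, Tukey fences (1.5 IQR beyond the quartiles) are
#' applied to the quadrant-averaged `sigma_int` and `beta`; a subject is
#' an outlier if either parameter falls outside its group's fences.
#'
#' @param lam Output of [fit_lam_table()].
#' @return `lam` with an added logical column `outlier`.
#' @export
flag_outlier_subjects <- function(lam) {
  means <- dplyr::summarise(
    dplyr::group_by(lam, .data$group, .data$subject_id),
    sigma_int = mean(.data$sigma_int),
    beta = mean(.data$beta),
    .groups = "drop_last"
  )
  means <- dplyr::mutate(
    means,
    outlier = !(iqr_keep(.data$sigma_int) & iqr_keep(.data$beta))
  )
  means <- dplyr::ungroup(means)
  dplyr::left_join(lam, means[, c("subject_id", "outlier")], by = "subject_id")
}

#' Group and quadrant inference on LAM parameters
#'
#' Reproduces the structure of the study's results section on any LAM
#' parameter table: rank-based Wald-type tests of the group effect and
#' group x hemifield interactions, within-group hemifield biases, the
#' same tests on within-subject quadrant ranks, Hodges-Lehmann
#' pseudo-medians per group (on quadrant-averaged values), and Spearman
#' correlations between internal noise and efficiency (per quadrant,
#' pooled over groups, and on quadrant-averaged values per group). All
#' p-values are reported raw; no multiplicity correction is applied.
#'
#' @param lam LAM parameter table ([fit_lam_table()]), optionally already
#'   passed through [flag_outlier_subjects()] (rows with `outlier == TRUE`
#'   are dropped here).
#' @return Tidy tibble with columns `analysis`, `parameter`, `group`,
#'   `term`, `statistic`, `df`, `p_value`, `estimate`, `conf_lo`,
#'   `conf_hi`, `n`.
#' @export
infer_effects <- function(lam) {
  lam <- tibble::as_tibble(lam)
  if ("outlier" %in% names(lam)) lam <- lam[!lam$outlier, ]
  if (nrow(lam) == 0) stop("no usable rows in LAM table")
  groups <- unique(lam$group)
  params <- c("sigma_int", "beta")
  out <- list()
  add <- function(...) out[[length(out) + 1]] <<- tibble::tibble(...)
  wts_row <- function(analysis, parameter, group_label, data, effect,
                      value = parameter) {
    w <- tryCatch(
      wald_type_statistic(data, value, effect, subject = "subject_id"),
      error = function(e) NULL
    )
    if (is.null(w)) {
      # degenerate cell (e.g. zero contrast variance in a tiny group):
      # report the effect as undefined rather than aborting the table
      add(analysis = analysis, parameter = parameter, group = group_label,
          term = effect, statistic = NA_real_, df = NA_integer_,
          p_value = NA_real_, estimate = NA_real_, conf_lo = NA_real_,
          conf_hi = NA_real_, n = length(unique(data$subject_id)))
    } else {
      add(analysis = analysis, parameter = parameter, group = group_label,
          term = effect, statistic = w$statistic, df = w$df,
          p_value = w$p_value, estimate = NA_real_, conf_lo = NA_real_,
          conf_hi = NA_real_, n = sum(w$n_per_group))
    }
  }
  between_effects <- c("group", "group:horizontal", "group:vertical")
  within_effects <- c("horizontal", "vertical")
  for (par in params) {
    if (length(groups) >= 2) {
      for (eff in between_effects) {
        wts_row("wts", par, "all", lam, eff)
      }
    }
    for (g in groups) {
      sub <- lam[lam$group == g, ]
      if (length(unique(sub$subject_id)) >= 2) {
        for (eff in within_effects) {
          wts_row("wts", par, g, sub, eff)
        }
      }
    }
    # quadrant-rank biases
    ranked <- quadrant_ranks(lam, par, subject = "subject_id")
    if (length(groups) >= 2) {
      for (eff in c("group:horizontal", "group:vertical")) {
        wts_row("wts_rank", par, "all", ranked, eff, value = "rank")
      }
    }
    for (g in groups) {
      sub <- ranked[ranked$group == g, ]
      if (length(unique(sub$subject_id)) >= 2) {
        for (eff in within_effects) {
          wts_row("wts_rank", par, g, sub, eff, value = "rank")
        }
      }
    }
    # group pseudo-medians of quadrant-averaged parameters
    for (g in groups) {
      vals <- dplyr::summarise(
        dplyr::group_by(lam[lam$group == g, ], .data$subject_id),
        v = mean(.data[[par]]), .groups = "drop"
      )$v
      if (length(vals) >= 3) {
        pm <- pseudo_median_ci(vals)
        add(analysis = "pseudo_median", parameter = par, group = g,
            term = "quadrant_mean", statistic = NA_real_, df = NA_integer_,
            p_value = NA_real_, estimate = pm$pseudo_median,
            conf_lo = pm$conf_lo, conf_hi = pm$conf_hi, n = pm$n)
      }
    }
  }
  # internal noise vs efficiency correlations
  for (q in quadrant_levels()) {
    sub <- lam[lam$quadrant == q, ]
    if (nrow(sub) >= 4) {
      sr <- spearman_rho(sub$sigma_int, sub$beta)
      add(analysis = "spearman", parameter = "sigma_int~beta", group = "all",
          term = q, statistic = sr$rho, df = NA_integer_,
          p_value = sr$p.value, estimate = sr$rho, conf_lo = NA_real_,
          conf_hi = NA_real_, n = sr$n)
    }
  }
  for (g in groups) {
    means <- dplyr::summarise(
      dplyr::group_by(lam[lam$group == g, ], .data$subject_id),
      sigma_int = mean(.data$sigma_int),
      beta = mean(.data$beta), .groups = "drop"
    )
    if (nrow(means) >= 4) {
      sr <- spearman_rho(means$sigma_int, means$beta)
      add(analysis = "spearman", parameter = "sigma_int~beta", group = g,
          term = "quadrant_mean", statistic = sr$rho, df = NA_integer_,
          p_value = sr$p.value, estimate = sr$rho, conf_lo = NA_real_,
          conf_hi = NA_real_, n = sr$n)
    }
  }
  dplyr::bind_rows(out)
}

#' Run the full simulation-and-analysis pipeline
#'
#' Generates a synthetic cohort, fits psychometric thresholds and LAM
#' parameters, flags outlier subjects, and computes the inference table.
#'
#' @param spec A [cohort_spec()].
#' @param task A [task_config()].
#' @param staircase A [staircase_config()].
#' @param sessions Staircase repeats per cell.
#' @param exclude_outliers Drop flagged subjects before inference?
#' @return Object of class `eqn_pipeline`: list with `trials`,
#'   `thresholds`, `lam` (with `outlier` column), `stats`, and the
#'   configurations used.
#' @examples
#' \donttest{
#' spec <- cohort_spec(groups = dplyr::mutate(default_groups(),
#'                                            n_subjects = c(4L, 4L)),
#'                     seed = 42)
#' res <- run_pipeline(spec)
#' res$stats
#' }
#' @export
run_pipeline <- function(spec, task = task_config(),
                         staircase = staircase_config(), sessions = 1,
                         exclude_outliers = TRUE) {
  trials <- generate_cohort(spec, task, staircase, sessions)
  thresholds <- fit_thresholds(trials, task = task)
  lam <- flag_outlier_subjects(fit_lam_table(thresholds, task$noise_levels))
  stats <- infer_effects(if (exclude_outliers) lam else
    dplyr::mutate(lam, outlier = FALSE))
  structure(
    list(trials = trials, thresholds = thresholds, lam = lam,
         stats = stats, spec = spec, task = task, staircase = staircase),
    class = "eqn_pipeline"
  )
}

#' @export
print.eqn_pipeline <- function(x, ...) {
  cat(sprintf(
    "<eqn_pipeline> %d trials, %d fitted cells, %d LAM rows (%d outliers)\n",
    nrow(x$trials), nrow(x$thresholds), nrow(x$lam), sum(x$lam$outlier)
  ))
  print(x$stats, n = 20)
  invisible(x)
}

#' Group-level threshold-versus-noise plot
#'
#' Median observed thresholds per group and noise level with the LAM curve
#' implied by each group's median parameters.
#'
#' @param thresholds Output of [fit_thresholds()].
#' @param lam Output of [fit_lam_table()].
#' @return A ggplot object.
#' @export
plot_group_lam <- function(thresholds, lam) {
  med_thr <- dplyr::summarise(
    dplyr::group_by(thresholds, .data$group, .data$noise_sd),
    threshold = stats::median(.data$threshold), .groups = "drop"
  )
  med_par <- dplyr::summarise(
    dplyr::group_by(lam, .data$group),
    sigma_int = stats::median(.data$sigma_int),
    beta = stats::median(.data$beta), .groups = "drop"
  )
  grid <- seq(0, max(med_thr$noise_sd) * 1.3, length.out = 120)
  curves <- dplyr::bind_rows(purrr::map(seq_len(nrow(med_par)), function(i) {
    tibble::tibble(
      group = med_par$group[i],
      noise_sd = grid,
      threshold = lam_threshold(grid, med_par$sigma_int[i], med_par$beta[i])
    )
  }))
  ggplot2::ggplot(med_thr, ggplot2::aes(x = .data$noise_sd,
                                        y = .data$threshold,
                                        colour = .data$group)) +
    ggplot2::geom_line(data = curves) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "External noise SD (deg)",
                  y = "Threshold amplitude (deg, log scale)",
                  colour = "Group")
}
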