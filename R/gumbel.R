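#' Gumbel psychometric function
#'
#' Probability of a correct response as a function of log10 curvature
#' amplitude:
#' `p = gamma + (1 - gamma - lambda) * (1 - exp(-10^(slope * (x - alpha))))`.
#' `gamma` is the guessing rate (fixed at 0.25 for the 4AFC task) and
#' `lambda` the lapse rate capping the upper asymptote at `1 - lambda`.
#' `alpha` is the threshold parameter: at `x = alpha` the function has
#' risen a fraction `1 - exp(-1)` of its range above the guess rate.
#'
#' @param x Log10 amplitude.
#' @param alpha Threshold parameter (log10 amplitude).
#' @param slope Slope parameter, > 0.
#' @param gamma Guess rate, default 0.25.
#' @param lambda Lapse rate in \[0, 0.05\].
#' @return Probability of a correct response.
#' @examples
#' gumbel_probability(-1, alpha = -1, slope = 2)
#' @export
gumbel_probability <- function(x, alpha, slope, gamma = 0.25, lambda = 0) {
  if (any(slope <= 0)) stop("`slope` must be positive")
  z <- slope * (x - alpha)
  z <- pmin(z, 30) # 10^30 underflows exp() to 0 anyway
  gamma + (1 - gamma - lambda) * (1 - exp(-10^z))
}

#' Bin trial records for psychometric fitting
#'
#' Aggregates trials into (amplitude, n_trials, n_correct) rows. Staircase
#' amplitudes lie on a multiplicative lattice, so amplitudes are matched
#' after rounding log10 amplitude to `digits` decimals.
#'
#' @param amplitude Numeric vector of trial amplitudes (> 0).
#' @param correct Logical vector of responses.
#' @param digits Decimals of log10 amplitude used for grouping.
#' @return Tibble with `amplitude`, `n_trials`, `n_correct`, sorted by
#'   amplitude.
#' @export
bin_trials <- function(amplitude, correct, digits = 6) {
  stopifnot(length(amplitude) == length(correct), all(amplitude > 0))
  key <- round(log10(amplitude), digits)
  u <- sort(unique(key))
  idx <- match(key, u)
  correct <- as.logical(correct)
  tibble::tibble(
    amplitude = 10^u,
    n_trials = tabulate(idx, length(u)),
    n_correct = tabulate(idx[correct], length(u))
  )
}

gumbel_nll <- function(par, x, n, k, gamma) {
  z <- 10^par[2] * (x - par[1])
  z[z > 30] <- 30
  p <- gamma + (1 - gamma - par[3]) * (1 - exp(-10^z))
  p[p < 1e-9] <- 1e-9
  p[p > 1 - 1e-9] <- 1 - 1e-9
  -sum(k * log(p) + (n - k) * log(1 - p))
}

# Analytic gradient of gumbel_nll (clamped regions contribute ~0).
gumbel_nll_grad <- function(par, x, n, k, gamma) {
  s <- 10^par[2]
  z <- s * (x - par[1])
  live <- z <= 30
  z[!live] <- 30
  T10 <- 10^z
  E <- exp(-T10)
  range_ <- 1 - gamma - par[3]
  p <- gamma + range_ * (1 - E)
  p[p < 1e-9] <- 1e-9
  p[p > 1 - 1e-9] <- 1 - 1e-9
  dl_dp <- -(k / p - (n - k) / (1 - p))
  ln10 <- log(10)
  core <- range_ * E * T10 * ln10 * live
  c(
    sum(dl_dp * core * (-s)),
    sum(dl_dp * core * z * ln10),
    sum(dl_dp * (E - 1))
  )
}

#' Fit a Gumbel psychometric function by maximum likelihood
#'
#' Maximizes the binomial log-likelihood over (`alpha`, `slope`, `lambda`)
#' with the guess rate fixed (0.25 for 4AFC) and the lapse rate
#' box-constrained to \[0, `lapse_max`\]. A small multi-start grid over
#' `alpha` (data range) and slope (0.5-4) guards against local optima
#' before a bounded quasi-Newton refinement. The deviance against the
#' saturated binomial model is reported as the goodness-of-fit statistic.
#'
#' @param data Tibble/data frame with columns `amplitude`, `n_trials`,
#'   `n_correct` (see [bin_trials()]); at least 3 distinct amplitudes.
#' @param gamma Fixed guess rate.
#' @param lapse_max Upper bound on the lapse rate.
#' @param start Optional length-3 numeric `c(alpha, log10 slope, lambda)`
#'   used as the single start (skips the grid; used by bootstrap refits).
#' @return Object of class `eqn_psychfit`: list with `alpha`, `slope`,
#'   `lambda`, `gamma`, `threshold_amplitude` (`10^alpha`),
#'   `log_likelihood`, `deviance`, `df` (points minus 3 free parameters),
#'   `gof_p` (upper-tail chi-square p of the deviance), `at_boundary`
#'   flag (degenerate all-correct / all-wrong data or parameter at its
#'   box), `removed_points` (filled by [prune_top_points()]), `data`.
#' @examples
#' d <- tibble::tibble(
#'   amplitude = c(0.02, 0.05, 0.1, 0.2, 0.4),
#'   n_trials = 40, n_correct = c(12, 15, 27, 38, 40)
#' )
#' fit <- fit_gumbel(d)
#' fit$threshold_amplitude
#' @export
fit_gumbel <- function(data, gamma = 0.25, lapse_max = 0.05, start = NULL) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("amplitude", "n_trials", "n_correct") %in% names(data)))
  data <- data[data$n_trials > 0, ]
  if (nrow(data) < 3) stop("need at least 3 amplitudes with trials")
  stopifnot(all(data$n_correct >= 0), all(data$n_correct <= data$n_trials),
            all(data$amplitude > 0))
  x <- log10(data$amplitude)
  n <- data$n_trials
  k <- data$n_correct
  prop <- k / n
  boundary_data <- all(prop >= 1 - 1e-12) || all(prop <= gamma)
  lower <- c(min(x) - 2, -1.5, 0)
  upper <- c(max(x) + 2, 1.5, lapse_max)
  if (is.null(start)) {
    a_grid <- seq(min(x), max(x), length.out = 4)
    s_grid <- log10(c(0.5, 1, 2, 4))
    grid <- expand.grid(a = a_grid, s = s_grid)
    nlls <- vapply(seq_len(nrow(grid)), function(i) {
      gumbel_nll(c(grid$a[i], grid$s[i], 0.02), x, n, k, gamma)
    }, numeric(1))
    starts <- grid[order(nlls)[1:2], , drop = FALSE]
    starts <- lapply(seq_len(nrow(starts)), function(i) {
      c(starts$a[i], starts$s[i], 0.02)
    })
  } else {
    starts <- list(pmin(pmax(start, lower), upper))
  }
  best <- NULL
  for (st in starts) {
    opt <- try(stats::optim(
      st, gumbel_nll, gumbel_nll_grad,
      x = x, n = n, k = k, gamma = gamma,
      method = "L-BFGS-B", lower = lower, upper = upper,
      control = list(maxit = 200)
    ), silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("psychometric fit failed to converge from any start")
  par <- best$par
  ll <- -best$value
  p_hat <- pmin(pmax(prop, 1e-9), 1 - 1e-9)
  ll_sat <- sum(k * log(p_hat) + (n - k) * log(1 - p_hat))
  deviance <- max(0, 2 * (ll_sat - ll))
  df <- nrow(data) - 3L
  at_box <- any(abs(par[1:2] - lower[1:2]) < 1e-6) ||
    any(abs(par[1:2] - upper[1:2]) < 1e-6)
  structure(
    list(
      alpha = par[1],
      slope = 10^par[2],
      lambda = par[3],
      gamma = gamma,
      threshold_amplitude = 10^par[1],
      log_likelihood = ll,
      deviance = deviance,
      df = df,
      gof_p = if (df > 0) stats::pchisq(deviance, df, lower.tail = FALSE)
              else NA_real_,
      at_boundary = boundary_data || at_box,
      removed_points = numeric(0),
      data = data
    ),
    class = "eqn_psychfit"
  )
}

#' @export
print.eqn_psychfit <- function(x, ...) {
  cat(sprintf(
    paste0("<eqn_psychfit> threshold = %.4g deg (alpha = %.3f), ",
           "slope = %.3g, lapse = %.3g\n  deviance = %.3g on %d df%s%s\n"),
    x$threshold_amplitude, x$alpha, x$slope, x$lambda,
    x$deviance, x$df,
    if (x$at_boundary) " [boundary]" else "",
    if (length(x$removed_points)) {
      sprintf(" [%d point(s) removed]", length(x$removed_points))
    } else ""
  ))
  invisible(x)
}

#' Remove unreliable high-amplitude points before fitting
#'
#' Very strongly curved contours can become hard to discriminate again,
#' producing non-monotonic psychometric data at the top of the amplitude
#' range. Following a chi-square goodness-of-fit screen, the single
#' highest-amplitude point is dropped when (a) the current fit is poor
#' (goodness-of-fit p < `p_poor`) and (b) dropping the point improves the
#' deviance by more than the chi-square(1) critical value at `p_improve`.
#' At most `max_remove` points are removed and at least 3 must remain.
#'
#' @param data Binned data as for [fit_gumbel()].
#' @param gamma,lapse_max Passed to [fit_gumbel()].
#' @param p_poor Significance level declaring a poor fit (default 0.05).
#' @param p_improve Significance level for the deviance improvement.
#' @param max_remove Cap on removed points (default 2).
#' @return The final `eqn_psychfit`, with `removed_points` holding the
#'   amplitudes that were dropped.
#' @export
prune_top_points <- function(data, gamma = 0.25, lapse_max = 0.05,
                             p_poor = 0.05, p_improve = 0.05,
                             max_remove = 2) {
  data <- tibble::as_tibble(data)
  removed <- numeric(0)
  fit <- fit_gumbel(data, gamma, lapse_max)
  crit <- stats::qchisq(1 - p_improve, df = 1)
  while (length(removed) < max_remove &&
           nrow(data) > 3 &&
           !is.na(fit$gof_p) && fit$gof_p < p_poor) {
    top <- which.max(data$amplitude)
    reduced <- data[-top, ]
    fit_red <- fit_gumbel(reduced, gamma, lapse_max)
    if (fit$deviance - fit_red$deviance > crit) {
      removed <- c(removed, data$amplitude[top])
      data <- reduced
      fit <- fit_red
    } else {
      break
    }
  }
  fit$removed_points <- removed
  fit
}

#' Bootstrap confidence interval for the psychometric threshold
#'
#' Nonparametric bootstrap over trials: within each amplitude the number
#' correct is resampled binomially at the observed proportion, the fit is
#' repeated from the original solution, and percentile intervals for
#' `alpha` are returned.
#'
#' @param fit An `eqn_psychfit`.
#' @param n_boot Number of resamples.
#' @param level Confidence level.
#' @return Tibble with `alpha_lo`, `alpha_hi`, `threshold_lo`,
#'   `threshold_hi`, `n_boot`.
#' @export
bootstrap_psychfit <- function(fit, n_boot = 200, level = 0.95) {
  data <- fit$data
  start <- c(fit$alpha, log10(fit$slope), fit$lambda)
  alphas <- vapply(seq_len(n_boot), function(b) {
    kb <- stats::rbinom(nrow(data), data$n_trials,
                        data$n_correct / data$n_trials)
    db <- data
    db$n_correct <- kb
    fb <- try(fit_gumbel(db, fit$gamma, start = start), silent = TRUE)
    if (inherits(fb, "try-error")) NA_real_ else fb$alpha
  }, numeric(1))
  qs <- stats::quantile(alphas, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  tibble::tibble(
    alpha_lo = qs[1], alpha_hi = qs[2],
    threshold_lo = 10^qs[1], threshold_hi = 10^qs[2],
    n_boot = as.integer(n_boot)
  )
}

#' @export
tidy.eqn_psychfit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "slope", "lambda", "gamma"),
    estimate = c(x$alpha, x$slope, x$lambda, x$gamma),
    fixed = c(FALSE, FALSE, FALSE, TRUE)
  )
}

#' @export
glance.eqn_psychfit <- function(x, ...) {
  tibble::tibble(
    threshold_amplitude = x$threshold_amplitude,
    log_likelihood = x$log_likelihood,
    deviance = x$deviance,
    df = x$df,
    gof_p = x$gof_p,
    at_boundary = x$at_boundary,
    n_removed = length(x$removed_points),
    n_points = nrow(x$data),
    n_trials = sum(x$data$n_trials)
  )
}

#' @export
autoplot.eqn_psychfit <- function(object, ...) {
  d <- object$data
  xs <- seq(min(log10(d$amplitude)) - 0.1, max(log10(d$amplitude)) + 0.1,
            length.out = 200)
  curve <- tibble::tibble(
    amplitude = 10^xs,
    p = gumbel_probability(xs, object$alpha, object$slope,
                           object$gamma, object$lambda)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$amplitude)) +
    ggplot2::geom_line(data = curve, ggplot2::aes(y = .data$p)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$n_correct / .data$n_trials,
                                     size = .data$n_trials)) +
    ggplot2::geom_hline(yintercept = object$gamma, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Amplitude (deg)", y = "Proportion correct",
                  size = "Trials")
}
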