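#' Linear Amplifier Model threshold
#'
#' The two-parameter Linear Amplifier Model (LAM) predicts the
#' discrimination threshold at external noise level `sigma_external` as
#' `A = sqrt(sigma_external^2 + sigma_internal^2) / beta`. Below the
#' equivalent-noise point (`sigma_external < sigma_internal`) thresholds
#' are flat and limited by internal noise; beyond it they rise in
#' proportion to the external noise. `beta` is the processing efficiency:
#' it scales thresholds down at every noise level without moving the knee.
#'
#' @param sigma_external External orientation-noise SD, degrees >= 0.
#' @param sigma_internal Equivalent internal noise SD, degrees >= 0.
#' @param beta Efficiency, > 0 (degrees of orientation per degree of
#'   amplitude).
#' @return Predicted threshold amplitude in degrees.
#' @examples
#' lam_threshold(c(0, 8, 16), sigma_internal = 6, beta = 2)
#' @export
lam_threshold <- function(sigma_external, sigma_internal, beta) {
  if (any(beta <= 0)) stop("`beta` must be positive")
  if (any(sigma_external < 0) || any(sigma_internal < 0)) {
    stop("noise SDs must be non-negative")
  }
  sqrt(sigma_external^2 + sigma_internal^2) / beta
}

#' Fit the Linear Amplifier Model to a threshold-versus-noise triple
#'
#' Least squares in log10 threshold (constant multiplicative threshold
#' error, matching staircase-derived thresholds) over
#' `sigma_internal in [0, 90]` and `beta > 0`, searched in log-parameter
#' space from a closed-form initial guess. With three noise levels and two
#' parameters the fit is near-interpolating; boundary solutions (e.g.
#' thresholds that fall with increasing noise, driving `sigma_internal`
#' to 0) are flagged rather than rejected.
#'
#' @param sigma_external Numeric vector of external-noise SDs (degrees),
#'   typically `c(0, 8, 16)`.
#' @param thresholds Positive threshold amplitudes, one per noise level.
#' @param sigma_max Upper bound for `sigma_internal` (degrees).
#' @return Object of class `eqn_lamfit`: list with `sigma_internal`,
#'   `beta`, `rss_log` (residual sum of squares in log10 threshold),
#'   `at_boundary`, `sigma_external`, `thresholds`, `fitted`.
#' @examples
#' A <- lam_threshold(c(0, 8, 16), 6, 1.2)
#' fit_lam(c(0, 8, 16), A)
#' @export
fit_lam <- function(sigma_external, thresholds, sigma_max = 90) {
  stopifnot(length(sigma_external) == length(thresholds),
            length(thresholds) >= 2)
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  if (any(sigma_external < 0)) stop("external noise must be non-negative")
  ly <- log10(thresholds)
  obj <- function(par) {
    s <- exp(par[1])
    b <- exp(par[2])
    sum((ly - log10(lam_threshold(sigma_external, s, b)))^2)
  }
  # closed-form guess from the lowest and highest noise levels
  i0 <- which.min(sigma_external)
  i1 <- which.max(sigma_external)
  r <- max(thresholds[i1] / thresholds[i0], 1 + 1e-6)
  s0 <- sigma_external[i1] / sqrt(max(r^2 - 1, 1e-6))
  s0 <- min(max(s0, 1e-3), sigma_max)
  b0 <- max(s0 / thresholds[i0], 1e-4)
  lower <- c(log(1e-6), log(1e-4))
  upper <- c(log(sigma_max), log(1e4))
  opt <- stats::optim(
    pmin(pmax(c(log(s0), log(b0)), lower), upper), obj,
    method = "L-BFGS-B", lower = lower, upper = upper,
    control = list(maxit = 500, factr = 1e4)
  )
  s_hat <- exp(opt$par[1])
  b_hat <- exp(opt$par[2])
  at_boundary <- s_hat <= 1e-5 || s_hat >= sigma_max * (1 - 1e-6) ||
    b_hat <= 1.0001e-4 || b_hat >= 1e4 * (1 - 1e-6)
  if (s_hat <= 1e-5) s_hat <- 0
  structure(
    list(
      sigma_internal = s_hat,
      beta = b_hat,
      rss_log = opt$value,
      at_boundary = at_boundary,
      sigma_external = sigma_external,
      thresholds = thresholds,
      fitted = lam_threshold(sigma_external, max(s_hat, 0), b_hat)
    ),
    class = "eqn_lamfit"
  )
}

#' @export
print.eqn_lamfit <- function(x, ...) {
  cat(sprintf(
    "<eqn_lamfit> sigma_internal = %.4g deg, beta = %.4g (rss_log = %.3g)%s\n",
    x$sigma_internal, x$beta, x$rss_log,
    if (x$at_boundary) " [boundary]" else ""
  ))
  invisible(x)
}

#' @export
tidy.eqn_lamfit <- function(x, ...) {
  tibble::tibble(
    term = c("sigma_internal", "beta"),
    estimate = c(x$sigma_internal, x$beta)
  )
}

#' @export
glance.eqn_lamfit <- function(x, ...) {
  tibble::tibble(
    sigma_internal = x$sigma_internal,
    beta = x$beta,
    rss_log = x$rss_log,
    at_boundary = x$at_boundary,
    n_levels = length(x$sigma_external)
  )
}

#' @export
autoplot.eqn_lamfit <- function(object, ...) {
  grid <- seq(0, max(object$sigma_external) * 1.3, length.out = 200)
  curve <- tibble::tibble(
    sigma_external = grid,
    threshold = lam_threshold(grid, object$sigma_internal, object$beta)
  )
  obs <- tibble::tibble(
    sigma_external = object$sigma_external,
    threshold = object$thresholds
  )
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$sigma_external,
                                    y = .data$threshold)) +
    ggplot2::geom_line(data = curve) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = object$sigma_internal,
                        linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "External noise SD (deg)",
                  y = "Threshold amplitude (deg, log scale)")
}

#' Tukey fences on a parameter vector
#'
#' Flags values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles by
#' linear interpolation (R quantile type 7). Used per group and per LAM
#' parameter (on quadrant-averaged values) to exclude outlier subjects.
#'
#' @param values Numeric vector; with fewer than 4 values no filtering is
#'   done (all kept, with a warning).
#' @param k Fence multiplier (1.5).
#' @return Logical keep-mask of the same length.
#' @examples
#' iqr_keep(c(1, 2, 3, 4, 100))
#' @export
iqr_keep <- function(values, k = 1.5) {
  if (length(values) < 4) {
    warning("fewer than 4 values; IQR outlier filtering skipped")
    return(rep(TRUE, length(values)))
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  values >= q[1] - k * iqr & values <= q[2] + k * iqr
}
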