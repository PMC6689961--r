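#' Per-cell relative treatment effects
#'
#' Rank-based effect sizes for a mixed factorial design with one
#' between-subjects factor (group) and the 2 x 2 within-subject layout of
#' visual-field quadrants. All observations are pooled and mid-ranked;
#' the relative effect of a group x quadrant cell is
#' `(mean rank - 0.5) / N_total`, the probability that an observation from
#' that cell exceeds an observation drawn at random from the pooled
#' design. Under exchangeability every relative effect is 0.5.
#'
#' @param data Long tibble with one row per subject x quadrant.
#' @param value Name of the response column (string).
#' @param subject,group,quadrant Column names (strings) identifying the
#'   design; `quadrant` must use the codes `UL`, `UR`, `LL`, `LR`.
#' @return Tibble with `group`, `quadrant`, `relative_effect`, `n_subjects`.
#' @examples
#' d <- tidyr::expand_grid(subject = 1:6, quadrant = quadrant_levels())
#' d$group <- ifelse(d$subject <= 3, "a", "b")
#' d$y <- seq_len(nrow(d))
#' relative_effects(d, "y")
#' @export
relative_effects <- function(data, value, subject = "subject",
                             group = "group", quadrant = "quadrant") {
  m <- factorial_matrix(data, value, subject, group, quadrant)
  N <- length(m$ranks)
  eff <- tibble::as_tibble(expand.grid(
    quadrant = quadrant_levels(), group = m$group_levels,
    stringsAsFactors = FALSE
  ))[, c("group", "quadrant")]
  eff$relative_effect <- as.vector(vapply(
    m$group_levels,
    function(g) (colMeans(m$ranks[m$groups == g, , drop = FALSE]) - 0.5) / N,
    numeric(4)
  ))
  eff$n_subjects <- rep(as.integer(table(m$groups)[m$group_levels]), each = 4)
  eff <- dplyr::arrange(eff, .data$group, match(.data$quadrant, quadrant_levels()))
  eff
}

# Reshape long data to a subjects x 4 quadrant-cell matrix plus pooled
# mid-ranks of every observation.
factorial_matrix <- function(data, value, subject, group, quadrant) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c(value, subject, group, quadrant) %in% names(data)))
  wide <- tidyr::pivot_wider(
    data[, c(subject, group, quadrant, value)],
    names_from = dplyr::all_of(quadrant),
    values_from = dplyr::all_of(value)
  )
  if (!all(quadrant_levels() %in% names(wide))) {
    stop("every subject needs all four quadrants ",
         paste(quadrant_levels(), collapse = ", "))
  }
  X <- as.matrix(wide[, quadrant_levels()])
  if (anyNA(X)) stop("incomplete quadrant data: every subject needs all four cells")
  groups <- as.character(wide[[group]])
  group_levels <- unique(groups)
  if (any(table(groups) < 2)) stop("every group needs at least 2 subjects")
  ranks <- matrix(rank(as.vector(X), ties.method = "average"),
                  nrow = nrow(X), ncol = 4, dimnames = list(NULL, colnames(X)))
  list(X = X, ranks = ranks, groups = groups, group_levels = group_levels,
       subjects = wide[[subject]])
}

# Moore-Penrose pseudo-inverse (SVD) with numerical rank.
pseudo_inverse <- function(M, tol = NULL) {
  sv <- svd(M)
  if (is.null(tol)) tol <- max(dim(M)) * max(sv$d, 0) * .Machine$double.eps
  keep <- sv$d > tol
  r <- sum(keep)
  if (r == 0) return(list(inv = matrix(0, ncol(M), nrow(M)), rank = 0L))
  inv <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  list(inv = inv, rank = as.integer(r))
}

# Contrast matrix for one effect, given group levels.
# Cells per group ordered UL, UR, LL, LR; vertical = upper vs lower,
# horizontal = left vs right.
wts_contrast <- function(effect, a) {
  w_vert <- c(1, 1, -1, -1) / 2
  w_horiz <- c(1, -1, 1, -1) / 2
  w_vh <- c(1, -1, -1, 1) / 2
  avg4 <- rep(1 / 4, 4)
  avg_g <- matrix(1 / a, 1, a)
  diff_g <- if (a >= 2) cbind(diag(a - 1), -1) else NULL
  kron <- function(G, w) kronecker(G, matrix(w, 1, 4))
  between <- c("group")
  if (effect %in% c("vertical", "horizontal", "vertical:horizontal")) {
    w <- switch(effect, vertical = w_vert, horizontal = w_horiz,
                `vertical:horizontal` = w_vh)
    return(kron(avg_g, w))
  }
  if (a < 2) stop("effect '", effect, "' needs at least two groups")
  switch(effect,
    group = kron(diff_g, avg4),
    `group:vertical` = kron(diff_g, w_vert),
    `group:horizontal` = kron(diff_g, w_horiz),
    `group:vertical:horizontal` = kron(diff_g, w_vh),
    stop("unknown effect: ", effect)
  )
}

#' Rank-based Wald-type statistic for the mixed factorial design
#'
#' Nonparametric analogue of the mixed-design factorial ANOVA for one
#' between-subjects factor (group) crossed with the 2 x 2 within-subject
#' visual-field factors (vertical: upper/lower; horizontal: left/right).
#' The statistic is the quadratic form
#' `WTS = (C p)' (C V C')^+ (C p)` in the estimated relative effects `p`,
#' where `V` is the block-diagonal covariance estimate built from the
#' between-subject empirical covariance of within-subject rank vectors in
#' each group, and `C` the effect's contrast matrix. `WTS` is referred to
#' a chi-square distribution with `df = rank(C V C')`. A singular
#' contrasted covariance is handled by the Moore-Penrose inverse and
#' flagged.
#'
#' @inheritParams relative_effects
#' @param effect One of `"group"`, `"vertical"`, `"horizontal"`,
#'   `"group:vertical"`, `"group:horizontal"`, `"vertical:horizontal"`,
#'   `"group:vertical:horizontal"`. Within-subject effects are averaged
#'   over groups; purely within effects also work on single-group data.
#' @return Object of class `eqn_wts`: list with `effect`, `statistic`,
#'   `df`, `p_value`, `relative_effects` (tibble), `contrast`, `singular`.
#' @examples
#' d <- tidyr::expand_grid(subject = 1:10, quadrant = quadrant_levels())
#' d$group <- ifelse(d$subject <= 5, "ctrl", "case")
#' set.seed(1); d$y <- rnorm(nrow(d)) + (d$group == "case")
#' wald_type_statistic(d, "y", effect = "group")
#' @export
wald_type_statistic <- function(data, value, effect = "group",
                                subject = "subject", group = "group",
                                quadrant = "quadrant") {
  m <- factorial_matrix(data, value, subject, group, quadrant)
  a <- length(m$group_levels)
  N <- length(m$ranks)
  p_hat <- as.vector(vapply(
    m$group_levels,
    function(g) (colMeans(m$ranks[m$groups == g, , drop = FALSE]) - 0.5) / N,
    numeric(4)
  ))
  V <- matrix(0, 4 * a, 4 * a)
  for (i in seq_len(a)) {
    Rg <- m$ranks[m$groups == m$group_levels[i], , drop = FALSE]
    ng <- nrow(Rg)
    idx <- (i - 1) * 4 + 1:4
    V[idx, idx] <- stats::cov(Rg) / (ng * N^2)
  }
  C <- wts_contrast(effect, a)
  Cp <- C %*% p_hat
  CVC <- C %*% V %*% t(C)
  pi_ <- pseudo_inverse(CVC)
  if (pi_$rank == 0) stop("contrasted covariance has rank 0; WTS undefined")
  wts <- drop(t(Cp) %*% pi_$inv %*% Cp)
  df <- pi_$rank
  eff_tbl <- tibble::as_tibble(expand.grid(
    quadrant = quadrant_levels(), group = m$group_levels,
    stringsAsFactors = FALSE
  ))[, c("group", "quadrant")]
  eff_tbl$relative_effect <- p_hat
  structure(
    list(
      effect = effect,
      statistic = wts,
      df = df,
      p_value = stats::pchisq(wts, df, lower.tail = FALSE),
      relative_effects = eff_tbl,
      contrast = C,
      singular = pi_$rank < nrow(C),
      n_per_group = table(m$groups)[m$group_levels]
    ),
    class = "eqn_wts"
  )
}

#' @export
print.eqn_wts <- function(x, ...) {
  cat(sprintf(
    "<eqn_wts> effect %s: WTS = %.3g, df = %d, p = %.4g%s\n",
    x$effect, x$statistic, x$df, x$p_value,
    if (x$singular) " [singular covariance]" else ""
  ))
  invisible(x)
}

#' @export
tidy.eqn_wts <- function(x, ...) {
  tibble::tibble(
    effect = x$effect,
    statistic = x$statistic,
    df = x$df,
    p.value = x$p_value
  )
}

#' Within-subject quadrant ranks
#'
#' Ranks each subject's four quadrant values 1-4 (mid-ranks for ties),
#' the transform used before testing quadrant biases on rank scores.
#'
#' @inheritParams relative_effects
#' @return `data` with the value column replaced by its within-subject
#'   rank (column renamed `rank`).
#' @examples
#' d <- tibble::tibble(subject = 1, group = "g",
#'                     quadrant = quadrant_levels(), y = c(5, 5, 1, 9))
#' quadrant_ranks(d, "y")$rank
#' @export
quadrant_ranks <- function(data, value, subject = "subject",
                           group = "group", quadrant = "quadrant") {
  data <- tibble::as_tibble(data)
  out <- dplyr::mutate(
    dplyr::group_by(data, dplyr::across(dplyr::all_of(subject))),
    rank = rank(.data[[value]], ties.method = "average")
  )
  out <- dplyr::ungroup(out)
  out[[value]] <- NULL
  out
}

#' Hodges-Lehmann pseudo-median with signed-rank confidence interval
#'
#' The one-sample Hodges-Lehmann estimator: the median of all Walsh
#' averages `(x[i] + x[j]) / 2` for `i <= j`. The confidence interval is
#' read off the ordered Walsh averages at Wilcoxon signed-rank critical
#' values (exact quantiles up to `n = 25`, normal approximation beyond).
#'
#' @param values Numeric vector, `n >= 3`.
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble with `pseudo_median`, `conf_lo`, `conf_hi`, `n`.
#' @examples
#' pseudo_median_ci(c(1, 2, 3))
#' @export
pseudo_median_ci <- function(values, conf_level = 0.95) {
  n <- length(values)
  stopifnot(n >= 3)
  w <- outer(values, values, `+`)[upper.tri(matrix(0, n, n), diag = TRUE)] / 2
  w <- sort(w)
  M <- n * (n + 1) / 2
  alpha <- 1 - conf_level
  k <- if (n <= 25) {
    stats::qsignrank(alpha / 2, n)
  } else {
    floor(M / 2 - stats::qnorm(1 - alpha / 2) *
            sqrt(n * (n + 1) * (2 * n + 1) / 24))
  }
  k <- max(min(k, floor(M / 2)), 0)
  tibble::tibble(
    pseudo_median = stats::median(w),
    conf_lo = w[k + 1],
    conf_hi = w[M - k],
    n = as.integer(n)
  )
}

#' Spearman rank correlation with t approximation
#'
#' Pearson correlation of mid-ranks; the p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom,
#' which accommodates ties.
#'
#' @param x,y Numeric vectors of equal length `>= 4`.
#' @return Tibble with `rho`, `p.value`, `n`.
#' @examples
#' spearman_rho(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("zero variance in ranks; correlation undefined")
    return(tibble::tibble(rho = NA_real_, p.value = NA_real_,
                          n = length(x)))
  }
  rho <- stats::cor(rx, ry)
  n <- length(x)
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  tibble::tibble(rho = rho, p.value = p, n = as.integer(n))
}
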