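test_that("identical value sets in both groups give relative effects of one half", {
  # each subject is constant over quadrants, so every cell holds the
  # same pooled value set and all cells are exchangeable
  d <- tibble::tibble(
    subject = rep(1:4, each = 4),
    group = rep(c("a", "a", "b", "b"), each = 4),
    quadrant = rep(quadrant_levels(), 4),
    y = rep(c(3, 1, 1, 3), each = 4)
  )
  eff <- relative_effects(d, "y")
  expect_equal(eff$relative_effect, rep(0.5, 8))
})

test_that("a stochastically dominant group has relative effects above one half", {
  set.seed(41)
  d <- factorial_data(5, 5, shift = 50)
  eff <- relative_effects(d, "y")
  expect_true(all(eff$relative_effect[eff$group == "b"] > 0.5))
  expect_true(all(eff$relative_effect[eff$group == "a"] < 0.5))
})

test_that("relative effects match hand-computed mid-ranks on an enumerable design", {
  # 4 subjects x 4 cells holding the values 1..16: pooled ranks equal the
  # values, so each cell's relative effect is (mean(value) - 0.5) / 16
  X <- matrix(c(1, 5, 9, 13,
                2, 6, 10, 14,
                3, 7, 11, 15,
                4, 8, 12, 16), nrow = 4, byrow = TRUE)
  d <- tibble::tibble(
    subject = rep(1:4, each = 4),
    group = rep(c("a", "a", "b", "b"), each = 4),
    quadrant = rep(quadrant_levels(), 4),
    y = as.vector(t(X))
  )
  eff <- relative_effects(d, "y")
  hand <- c(colMeans(X[1:2, ]), colMeans(X[3:4, ]))
  expect_equal(eff$relative_effect, (hand - 0.5) / 16)
})

test_that("relative effects are invariant under strictly monotone transforms", {
  set.seed(42)
  d <- factorial_data(6, 5, shift = 0.5)
  base <- relative_effects(d, "y")$relative_effect
  for (f in list(function(x) exp(x), function(x) x^3,
                 function(x) rank(x) + 0.1 * rank(x)^2)) {
    d2 <- d
    d2$y <- f(d$y)
    expect_equal(relative_effects(d2, "y")$relative_effect, base)
  }
})

test_that("the Wald-type statistic separates shifted groups decisively", {
  set.seed(43)
  d <- factorial_data(10, 10, shift = 100)
  w <- wald_type_statistic(d, "y", "group")
  expect_lt(w$p_value, 0.001)
  expect_equal(w$df, 1L)
})

test_that("WTS is invariant to consistent relabeling of within-subject cells", {
  set.seed(44)
  d <- factorial_data(8, 7, quadrant_shift = c(1, 0, 0.5, 0))
  w_vert <- wald_type_statistic(d, "y", "vertical")
  # swap UR <-> LL: the vertical contrast of the relabeled data is the
  # horizontal contrast of the original
  d2 <- d
  d2$quadrant <- c(UL = "UL", UR = "LL", LL = "UR", LR = "LR")[d$quadrant]
  w_horiz_orig <- wald_type_statistic(d, "y", "horizontal")
  w_vert_relab <- wald_type_statistic(d2, "y", "vertical")
  expect_equal(w_vert_relab$statistic, w_horiz_orig$statistic,
               tolerance = 1e-10)
  expect_equal(w_vert_relab$p_value, w_horiz_orig$p_value, tolerance = 1e-10)
})

test_that("under the null the WTS p-value distribution is near uniform", {
  set.seed(45)
  pvals <- vapply(1:1000, function(i) {
    wald_type_statistic(factorial_data(20, 20), "y", "group")$p_value
  }, numeric(1))
  ks <- max(abs(sort(pvals) - (1:1000) / 1000))
  expect_lt(ks, 0.08)
})

test_that("wald_type_statistic validates the design", {
  set.seed(46)
  d <- factorial_data(4, 4)
  expect_error(wald_type_statistic(d[-1, ], "y", "group"), "four quadrants|incomplete")
  one <- d[d$group == "a", ]
  expect_error(wald_type_statistic(one, "y", "group"), "two groups")
  expect_s3_class(tidy(wald_type_statistic(one, "y", "vertical")),
                  "tbl_df")
})

test_that("quadrant ranks use mid-ranks and are permutation-equivariant", {
  d <- tibble::tibble(subject = 1, group = "g",
                      quadrant = quadrant_levels(), y = c(1, 2, 3, 4))
  expect_equal(quadrant_ranks(d, "y")$rank, c(1, 2, 3, 4))
  d$y <- c(5, 5, 1, 9)
  expect_equal(quadrant_ranks(d, "y")$rank, c(2.5, 2.5, 1, 4))
  perm <- c(3, 1, 4, 2)
  d2 <- d
  d2$y <- d$y[perm]
  expect_equal(quadrant_ranks(d2, "y")$rank,
               quadrant_ranks(d, "y")$rank[perm])
})

test_that("the pseudo-median matches Walsh-average enumeration and shifts correctly", {
  expect_equal(pseudo_median_ci(c(1, 2, 3))$pseudo_median, 2)
  set.seed(47)
  x <- rnorm(8)
  pm <- pseudo_median_ci(x)
  # exhaustive oracle: all 36 Walsh averages
  walsh <- c(outer(x, x, `+`)[upper.tri(matrix(0, 8, 8), diag = TRUE)]) / 2
  expect_length(walsh, 36)
  expect_equal(pm$pseudo_median, median(walsh))
  # independent implementation in stats::wilcox.test
  wt <- suppressWarnings(wilcox.test(x, conf.int = TRUE))
  expect_equal(pm$pseudo_median, unname(wt$estimate), tolerance = 1e-6)
  # shift equivariance
  pm2 <- pseudo_median_ci(x + 3.2)
  expect_equal(pm2$pseudo_median, pm$pseudo_median + 3.2)
  expect_equal(pm2$conf_lo, pm$conf_lo + 3.2)
  # large-sample branch stays close to the exact-quantile construction
  set.seed(48)
  y <- rnorm(40, mean = 2)
  pm3 <- pseudo_median_ci(y)
  wt3 <- suppressWarnings(wilcox.test(y, conf.int = TRUE))
  expect_equal(pm3$pseudo_median, unname(wt3$estimate), tolerance = 1e-6)
  expect_lt(abs(pm3$conf_lo - wt3$conf.int[1]), 0.1)
})

test_that("spearman_rho agrees with cor.test and handles ties", {
  x <- 1:6
  expect_equal(spearman_rho(x, x)$rho, 1)
  expect_equal(spearman_rho(x, rev(x))$rho, -1)
  y <- c(2, 2, 5, 1, 6, 4) # one tie
  mine <- spearman_rho(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(mine$rho, unname(ref$estimate))
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
  expect_warning(res <- spearman_rho(x, rep(1, 6)), "zero variance")
  expect_true(is.na(res$rho))
})
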