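test_that("zero curvature gives collinear points with chord-aligned tangents", {
  cfg <- task_config()
  p <- contour_path(0, cfg, chord_orientation = 30)
  expect_equal(p$tangents, rep(30, cfg$n_wavelets))
  # collinear: all points on the line through the first two
  d <- sweep(p$positions, 2, p$positions[1, ])
  cross <- d[, 1] * d[nrow(d), 2] - d[, 2] * d[nrow(d), 1]
  expect_equal(cross, rep(0, cfg$n_wavelets), tolerance = 1e-12)
  gaps <- sqrt(diff(d[, 1])^2 + diff(d[, 2])^2)
  expect_equal(gaps, rep(gaps[1], length(gaps)))
})

test_that("the middle element sits exactly one sagitta from the chord", {
  cfg <- task_config()
  for (A in c(0.05, 0.1, 0.25)) {
    p <- contour_path(A, cfg) # chord along x, centred at origin
    mid <- (cfg$n_wavelets + 1) / 2
    expect_equal(unname(p$positions[mid, 2]), A, tolerance = 1e-12)
    # chord endpoints stay put
    expect_equal(p$positions[1, ], c(x = -cfg$chord_length / 2, y = 0),
                 tolerance = 1e-12)
  }
})

test_that("tangent orientations are mirror-symmetric about the middle element", {
  cfg <- task_config()
  n <- cfg$n_wavelets
  for (A in seq(0.02, 0.29, length.out = 10)) {
    p <- contour_path(A, cfg, chord_orientation = 47)
    dev <- fold_orientation_diff(p$tangents - 47)
    expect_equal(dev, -rev(dev), tolerance = 1e-10)
    expect_equal(dev[(n + 1) / 2], 0, tolerance = 1e-10)
  }
})

test_that("contour_path rejects bad amplitudes", {
  expect_error(contour_path(-0.1, task_config()), "non-negative")
  expect_error(contour_path(0.8, task_config()), "minor arc")
})

test_that("distractor construction is a reflection about the chord (involution)", {
  cfg <- task_config()
  s_valid <- make_stimulus(0.15, TRUE, 0, "UR", cfg, chord_orientation = 20)
  s_dist <- make_stimulus(0.15, FALSE, 0, "UR", cfg, chord_orientation = 20)
  expect_equal(s_dist$element_positions, s_valid$element_positions)
  # reflecting the distractor orientations again returns the tangents
  back <- wrap_orientation(2 * 20 - s_dist$base_orientations)
  expect_equal(back, s_valid$base_orientations, tolerance = 1e-10)
})

test_that("noise-free valid stimuli are aligned with the path", {
  s <- make_stimulus(0.1, TRUE, 0, "LL", chord_orientation = 75)
  expect_equal(s$jittered_orientations, s$base_orientations)
  expect_equal(s$base_orientations, s$valid_orientations)
})

test_that("the orientation-noise injector has the configured SD", {
  set.seed(42)
  cfg <- task_config()
  diffs <- unlist(lapply(seq_len(ceiling(10000 / cfg$n_wavelets)), function(i) {
    s <- make_stimulus(0.1, TRUE, 16, "UL", cfg,
                       chord_orientation = runif(1, 0, 180))
    fold_orientation_diff(s$jittered_orientations - s$base_orientations)
  }))
  expect_gt(length(diffs), 9999)
  expect_lt(abs(sd(diffs) - 16), 0.5)
})

test_that("valid/distractor orientation difference is odd in amplitude and vanishes at 0", {
  cfg <- task_config()
  grid <- seq(0.02, 0.28, length.out = 8)
  diff_at <- function(A, sign) {
    p <- contour_path(A, cfg, chord_orientation = 0, curvature_sign = sign)
    fold_orientation_diff(p$tangents - wrap_orientation(-p$tangents))
  }
  for (A in grid) {
    expect_equal(diff_at(A, 1), -diff_at(A, -1), tolerance = 1e-10)
  }
  s0v <- make_stimulus(0, TRUE, 0, "UL", cfg, chord_orientation = 10)
  s0d <- make_stimulus(0, FALSE, 0, "UL", cfg, chord_orientation = 10)
  expect_equal(s0v$base_orientations, s0d$base_orientations)
})

test_that("folded valid-distractor separation grows with amplitude over the operating range", {
  cfg <- task_config()
  grid <- seq(0, 0.28, length.out = 12)
  sep <- vapply(grid, function(A) {
    v <- make_stimulus(A, TRUE, 0, "UL", cfg, chord_orientation = 0)
    mean(abs(fold_orientation_diff(
      v$valid_orientations - v$distractor_orientations
    )))
  }, numeric(1))
  expect_true(all(diff(sep) >= -1e-10))
  expect_equal(sep[1], 0)
})

test_that("geometry is seed-invariant; only the jitter is random", {
  set.seed(1)
  a <- make_stimulus(0.1, TRUE, 8, "UR", chord_orientation = 33)
  set.seed(2)
  b <- make_stimulus(0.1, TRUE, 8, "UR", chord_orientation = 33)
  expect_equal(a$base_orientations, b$base_orientations)
  expect_equal(a$element_positions, b$element_positions)
  expect_false(isTRUE(all.equal(a$jittered_orientations,
                                b$jittered_orientations)))
})

test_that("rendering is deterministic and reflects stimulus identity", {
  cfg <- task_config()
  s <- make_stimulus(0.1, TRUE, 0, "UL", cfg)
  img1 <- render_stimulus(s, cfg, size_deg = 2.2)
  img2 <- render_stimulus(s, cfg, size_deg = 2.2)
  expect_identical(img1, img2)
  expect_true(all(img1 >= 0 & img1 <= 1))
  # at zero curvature the reflection fixes every tangent: same image
  v0 <- make_stimulus(0, TRUE, 0, "UR", cfg, chord_orientation = 40)
  d0 <- make_stimulus(0, FALSE, 0, "UR", cfg, chord_orientation = 40)
  expect_equal(render_stimulus(v0, cfg), render_stimulus(d0, cfg))
  # an element pushed out of frame is an error
  s_far <- make_stimulus(0.1, TRUE, 0, "UL", cfg)
  s_far$element_positions[1, ] <- c(50, 50)
  expect_error(render_stimulus(s_far, cfg), "outside")
})

test_that("stimulus JSON serialization round-trips the orientations", {
  s <- make_stimulus(0.12, FALSE, 8, "LR", chord_orientation = 10)
  j <- jsonlite::fromJSON(stimulus_to_json(s))
  expect_equal(j$base_orientations, s$base_orientations, tolerance = 1e-12)
  expect_false(j$is_valid)
  expect_equal(j$quadrant, "LR")
})
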