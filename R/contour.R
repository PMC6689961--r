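#' Contour path geometry
#'
#' Places the contour elements on a circular arc. The arc's chord has
#' length `config$chord_length`, is centred on the quadrant centre, and is
#' rotated by `chord_orientation`; the curvature amplitude is the arc's
#' sagitta (perpendicular distance from the chord midpoint to the arc), in
#' degrees of visual angle. Elements are equally spaced in arc length and
#' each carries the local tangent orientation.
#'
#' At `amplitude = 0` the arc degenerates to the chord: elements are
#' collinear and every tangent equals the chord orientation.
#'
#' @param amplitude Sagitta in degrees of visual angle (>= 0). Must be
#'   less than half the chord length so the path stays a minor arc.
#' @param config A [task_config()].
#' @param chord_orientation Orientation of the chord in degrees.
#' @param curvature_sign +1 or -1, the side of the chord the arc bulges to.
#' @param center Length-2 numeric, quadrant centre in degrees (x, y).
#' @return A list with `positions` (n x 2 matrix, degrees) and
#'   `tangents` (length-n vector of orientations in `[0, 180)`).
#' @examples
#' p <- contour_path(0.1, task_config())
#' p$tangents
#' @export
contour_path <- function(amplitude, config = task_config(),
                         chord_orientation = 0, curvature_sign = 1,
                         center = c(0, 0)) {
  if (amplitude < 0) stop("`amplitude` (sagitta) must be non-negative")
  L <- config$chord_length
  if (amplitude >= L / 2) {
    stop("`amplitude` must be below half the chord length (minor arc)")
  }
  n <- config$n_wavelets
  s <- sign(curvature_sign)
  if (amplitude == 0) {
    t <- seq(-L / 2, L / 2, length.out = n)
    local <- cbind(t, rep(0, n))
    tang_local <- rep(0, n)
  } else {
    R <- amplitude / 2 + L^2 / (8 * amplitude)
    half <- asin(L / (2 * R))
    u <- seq(-half, half, length.out = n)
    local <- cbind(R * sin(u), s * (R * cos(u) - (R - amplitude)))
    # tangent of (R sin u, R cos u) is at angle -u from the chord
    tang_local <- -s * u * 180 / pi
  }
  phi <- chord_orientation * pi / 180
  rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  positions <- sweep(local %*% t(rot), 2, center, `+`)
  colnames(positions) <- c("x", "y")
  list(
    positions = positions,
    tangents = wrap_orientation(tang_local + chord_orientation)
  )
}

#' Construct one contour stimulus (valid target or distractor)
#'
#' A valid stimulus aligns each element with the local tangent of its
#' contour path; a distractor reflects each element's orientation about
#' the chord direction, which is exactly the orientation field of a
#' contour curving the opposite way (positions are unchanged). External
#' orientation noise adds an independent Normal(0, `noise_sd`) sample to
#' every element's orientation; base orientations and positions never
#' depend on the random-number state.
#'
#' @param amplitude Curvature amplitude (sagitta), degrees >= 0.
#' @param is_valid `TRUE` for the target, `FALSE` for a distractor.
#' @param noise_sd External orientation-noise SD, degrees >= 0.
#' @param quadrant One of `"UL"`, `"UR"`, `"LL"`, `"LR"`.
#' @param config A [task_config()].
#' @param chord_orientation,curvature_sign Path pose; see [contour_path()].
#' @return An object of class `eqn_stimulus`: a list with `quadrant`,
#'   `amplitude`, `is_valid`, `noise_sd`, `element_positions`,
#'   `base_orientations`, `jittered_orientations`, and the two orientation
#'   templates `valid_orientations` / `distractor_orientations` used by
#'   the simulated observer.
#' @examples
#' set.seed(1)
#' s <- make_stimulus(0.1, is_valid = TRUE, noise_sd = 8, quadrant = "UR")
#' s$jittered_orientations
#' @export
make_stimulus <- function(amplitude, is_valid, noise_sd, quadrant = "UL",
                          config = task_config(),
                          chord_orientation = 0, curvature_sign = 1) {
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  quadrant <- match.arg(quadrant, quadrant_levels())
  path <- contour_path(amplitude, config, chord_orientation, curvature_sign,
                       center = quadrant_center(quadrant, config))
  valid_ori <- path$tangents
  # reflect about the chord: theta -> 2*phi - theta (mod 180)
  distractor_ori <- wrap_orientation(2 * chord_orientation - valid_ori)
  base <- if (is_valid) valid_ori else distractor_ori
  jitter <- if (noise_sd == 0) {
    rep(0, config$n_wavelets)
  } else {
    stats::rnorm(config$n_wavelets, 0, noise_sd)
  }
  structure(
    list(
      quadrant = quadrant,
      amplitude = amplitude,
      is_valid = isTRUE(is_valid),
      noise_sd = noise_sd,
      chord_orientation = chord_orientation,
      element_positions = path$positions,
      base_orientations = base,
      jittered_orientations = wrap_orientation(base + jitter),
      valid_orientations = valid_ori,
      distractor_orientations = distractor_ori
    ),
    class = "eqn_stimulus"
  )
}

quadrant_center <- function(quadrant, config) {
  e <- config$eccentricity / sqrt(2)
  switch(quadrant,
    UL = c(-e, e), UR = c(e, e), LL = c(-e, -e), LR = c(e, -e)
  )
}

#' @export
print.eqn_stimulus <- function(x, ...) {
  cat(sprintf(
    "<eqn_stimulus> %s %s, amplitude %.4g deg, noise SD %g deg, %d elements\n",
    x$quadrant, if (x$is_valid) "target" else "distractor",
    x$amplitude, x$noise_sd, length(x$base_orientations)
  ))
  invisible(x)
}

#' Render a stimulus to a grayscale image (test fixture)
#'
#' Draws one cosine-phase oriented wavelet per element: a carrier grating
#' at the configured peak spatial frequency under a Gaussian envelope whose
#' full widths at half magnitude along and across the stripes come from the
#' task configuration. The analysis pipeline never operates on pixels; this
#' renderer exists so stimuli can be inspected and so fixtures are
#' reproducible. Rendering is deterministic given the stimulus.
#'
#' @param stim An [make_stimulus()] object.
#' @param config A [task_config()]; `pixels_per_deg` sets resolution.
#' @param size_deg Side length of the square canvas in degrees, centred on
#'   the stimulus quadrant centre.
#' @return A numeric matrix in `[0, 1]`, mid-gray background 0.5.
#' @export
render_stimulus <- function(stim, config = task_config(), size_deg = 2.5) {
  stopifnot(config$pixels_per_deg > 0)
  npx <- round(size_deg * config$pixels_per_deg)
  img <- matrix(0.5, npx, npx)
  if (length(stim$base_orientations) == 0) return(img)
  center <- quadrant_center(stim$quadrant, config)
  half <- size_deg / 2
  xs <- seq(center[1] - half, center[1] + half, length.out = npx)
  ys <- seq(center[2] + half, center[2] - half, length.out = npx) # row 1 = top
  # Gaussian envelope sigmas in degrees, from FWHM in carrier cycles
  cyc <- 1 / config$peak_sf
  sd_along <- config$fwhm_along * cyc / (2 * sqrt(2 * log(2)))
  sd_across <- config$fwhm_across * cyc / (2 * sqrt(2 * log(2)))
  pos <- stim$element_positions
  lim <- c(min(xs), max(xs), min(ys), max(ys))
  if (any(pos[, 1] < lim[1] | pos[, 1] > lim[2] |
            pos[, 2] < lim[3] | pos[, 2] > lim[4])) {
    stop("stimulus element falls outside the rendering frame")
  }
  gx <- matrix(xs, npx, npx, byrow = TRUE)
  gy <- matrix(ys, npx, npx)
  for (i in seq_along(stim$jittered_orientations)) {
    th <- stim$jittered_orientations[i] * pi / 180
    dx <- gx - pos[i, 1]
    dy <- gy - pos[i, 2]
    # along-stripe axis at orientation th; across is its normal
    a <- dx * cos(th) + dy * sin(th)
    b <- -dx * sin(th) + dy * cos(th)
    env <- exp(-0.5 * ((a / sd_along)^2 + (b / sd_across)^2))
    carrier <- cos(2 * pi * config$peak_sf * b) # cosine phase: white centre
    img <- img + 0.5 * env * carrier
  }
  pmin(pmax(img, 0), 1)
}

#' Write a rendered stimulus to PNG
#'
#' Thin wrapper around [render_stimulus()] using the `png` package.
#'
#' @inheritParams render_stimulus
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stimulus_png <- function(stim, path, config = task_config(),
                               size_deg = 2.5) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("package 'png' is required to write PNG fixtures")
  }
  png::writePNG(render_stimulus(stim, config, size_deg), path)
  invisible(path)
}

#' Serialize a stimulus to JSON
#'
#' @param stim An `eqn_stimulus`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string or `path` invisibly.
#' @export
stimulus_to_json <- function(stim, path = NULL) {
  obj <- unclass(stim)
  obj$element_positions <- as.data.frame(obj$element_positions)
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
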