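#' Angle arithmetic on the orientation circle
#'
#' Orientations of contour elements live on a circle of period 180 degrees
#' (a bar rotated by 180 degrees is the same bar). `wrap_orientation()`
#' reduces angles to `[0, 180)`; `fold_orientation_diff()` maps signed
#' orientation differences to the principal interval `(-90, 90]`, the
#' smallest rotation carrying one orientation onto the other.
#'
#' @param theta Numeric vector of angles in degrees.
#' @return Numeric vector of the same length, in degrees.
#' @examples
#' wrap_orientation(c(-10, 185, 90))
#' fold_orientation_diff(c(170, -170, 91))
#' @export
wrap_orientation <- function(theta) {
  theta %% 180
}

#' @rdname wrap_orientation
#' @export
fold_orientation_diff <- function(theta) {
  out <- (theta + 90) %% 180 - 90
  # map -90 to +90 so the interval is (-90, 90]
  out[out == -90] <- 90
  out
}
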