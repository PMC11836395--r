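# Planar geometry helpers shared by the simulator and the cohesion metric.
# Coordinates follow the image convention: x = column, y = row, 0-based,
# with real-valued (sub-pixel) positions; cm coordinates in the tank frame
# have their origin at the tank centre.

#' Area of a simple polygon (shoelace formula)
#' @param xy Two-column matrix of vertices in order.
#' @return Area (same squared units as the input), non-negative.
#' @keywords internal
#' @noRd
polygon_area <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  i2 <- c(2:n, 1)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

polygon_perimeter <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 2) return(0)
  i2 <- c(2:n, 1)
  sum(sqrt((xy[, 1] - xy[i2, 1])^2 + (xy[, 2] - xy[i2, 2])^2))
}

#' Area of the convex hull of a point set dilated by a disc of radius r
#'
#' The Minkowski sum of a convex polygon with a disc of radius `r` has area
#' `A + P * r + pi * r^2` (polygon area A, perimeter P); this is exact, and
#' degenerates gracefully: two points give a stadium, one point a disc.
#' @param xy Two-column matrix of points.
#' @param r Dilation radius, >= 0.
#' @keywords internal
#' @noRd
dilated_hull_area <- function(xy, r) {
  xy <- xy[complete.cases(xy), , drop = FALSE]
  n <- nrow(xy)
  if (n == 0) return(0)
  if (n == 1) return(pi * r^2)
  h <- grDevices::chull(xy)
  hull <- xy[h, , drop = FALSE]
  polygon_area(hull) + polygon_perimeter(hull) * r + pi * r^2
}

#' y-cut of a horizontal chord so that the region {y >= cut} has a given
#' fraction of the disc area (y grows downwards in image coordinates).
#' @keywords internal
#' @noRd
chord_cut_for_fraction <- function(radius, fraction) {
  if (fraction >= 1) return(-radius)
  if (fraction <= 0) stopf("monitored_fraction must be in (0, 1]")
  target <- fraction * pi * radius^2
  seg_area <- function(c) radius^2 * acos(clamp(c / radius, -1, 1)) -
    c * sqrt(pmax(radius^2 - c^2, 0))
  uniroot(function(c) seg_area(c) - target,
          lower = -radius, upper = radius, tol = 1e-10)$root
}

#' Logical raster of a disc, evaluated at pixel centres
#' @keywords internal
#' @noRd
disc_mask <- function(dim_hw, center_xy_px, radius_px) {
  h <- dim_hw[1]; w <- dim_hw[2]
  x <- matrix(rep(0:(w - 1), each = h), nrow = h)
  y <- matrix(rep(0:(h - 1), times = w), nrow = h)
  (x - center_xy_px[1])^2 + (y - center_xy_px[2])^2 <= radius_px^2
}
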