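#' Lithotripter focal zone geometry
#'
#' The focal zone is the region where the shockwave energy concentrates; a
#' shot "hits" when enough of the stone occupies it. Piezoelectric focal
#' zones are ellipsoidal, so the default shape is an axis-aligned ellipse in
#' the imaging plane; a rectangle is available for exact-arithmetic tests.
#'
#' Coordinates follow the image convention used throughout the package:
#' 0-based pixel coordinates, `x` along columns (left to right), `y` along
#' rows (top to bottom), with a pixel's coordinate at its centre.
#'
#' @param center Numeric length-2 `(x, y)` centre in pixels.
#' @param semi_axes Numeric length-2 `(a, b)` semi-axes in pixels (half
#'   width/height for a rectangle).
#' @param shape `"ellipse"` or `"rectangle"`.
#' @return An object of class `focal_zone`.
#' @export
focal_zone <- function(center, semi_axes, shape = c("ellipse", "rectangle")) {
  shape <- match.arg(shape)
  center <- as.numeric(center); semi_axes <- as.numeric(semi_axes)
  if (length(center) != 2L || length(semi_axes) != 2L)
    stop("center and semi_axes must have length 2")
  if (any(semi_axes <= 0)) stop("focal-zone semi-axes must be positive")
  structure(list(center = center, semi_axes = semi_axes, shape = shape),
            class = "focal_zone")
}

# 0/1 membership mask of a focal zone on an height x width pixel grid.
zone_mask <- function(zone, height, width) {
  stopifnot(inherits(zone, "focal_zone"))
  xs <- matrix(rep(0:(width - 1L), each = height), height, width)
  ys <- matrix(rep(0:(height - 1L), times = width), height, width)
  cx <- zone$center[1L]; cy <- zone$center[2L]
  a <- zone$semi_axes[1L]; b <- zone$semi_axes[2L]
  m <- if (zone$shape == "ellipse") {
    ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
  } else {
    abs(xs - cx) <= a & abs(ys - cy) <= b
  }
  if (!any(m)) stop("focal zone does not intersect the image")
  m * 1L
}

# 0/1 mask of an axis-aligned ellipse (used for kidney, stone, zone).
.ellipse_mask <- function(center, semi_axes, height, width) {
  xs <- matrix(rep(0:(width - 1L), each = height), height, width)
  ys <- matrix(rep(0:(height - 1L), times = width), height, width)
  (((xs - center[1L]) / semi_axes[1L])^2 +
     ((ys - center[2L]) / semi_axes[2L])^2 <= 1) * 1L
}
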