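#' Spherical coordinate frames for auditory direction data
#'
#' Two frames are used throughout the package, matching common practice in
#' head-related transfer function (HRTF) work with a motorized polar stage:
#'
#' * **front-Z** (`"front-z"`): the polar axis points rostrally (out of the
#'   nose). `azimuth` is the signed polar angle from the rostral axis
#'   (positive toward the animal's right), and `elevation` rotates around
#'   that axis from the horizontal plane toward dorsal. This is the frame of
#'   HRIR measurement grids and stimulus presentation.
#' * **top-Z** (`"top-z"`): the polar axis points dorsally (up); `azimuth`
#'   is the standard horizontal angle from straight ahead (positive right)
#'   and `elevation` the angle above the horizontal plane. Receptive-field
#'   fitting uses this frame because it has no azimuth discontinuity across
#'   the frontal midline.
#'
#' Both frames share the world Cartesian axes x = rostral, y = right,
#' z = dorsal, and agree on the horizontal plane (elevation 0). At a frame's
#' pole the azimuth (front-Z) or the elevation-complement (top-Z) is
#' degenerate; `unit_to_direction()` canonicalizes it to 0.
#'
#' @param azimuth,elevation angles in degrees (vectorized).
#' @param frame `"front-z"` or `"top-z"`.
#' @return `direction_to_unit()`: an `n x 3` matrix of unit vectors.
#' @examples
#' direction_to_unit(90, 0, "front-z") # straight right
#' @export
direction_to_unit <- function(azimuth, elevation, frame = c("front-z", "top-z")) {
  frame <- match.arg(frame)
  az <- deg2rad(azimuth)
  el <- deg2rad(elevation)
  if (frame == "top-z") {
    v <- cbind(cos(el) * cos(az), cos(el) * sin(az), sin(el))
  } else {
    v <- cbind(cos(az), sin(az) * cos(el), abs(sin(az)) * sin(el))
  }
  colnames(v) <- c("x", "y", "z")
  v
}

#' @rdname direction_to_unit
#' @param unit an `n x 3` matrix (or length-3 vector) of unit vectors in
#'   world coordinates (x rostral, y right, z dorsal).
#' @return `unit_to_direction()`: a data.frame with `azimuth` and
#'   `elevation` in degrees.
#' @export
unit_to_direction <- function(unit, frame = c("front-z", "top-z")) {
  frame <- match.arg(frame)
  if (is.null(dim(unit))) unit <- matrix(unit, nrow = 1)
  nrm <- sqrt(rowSums(unit^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    stop("`unit` rows must be unit vectors", call. = FALSE)
  }
  x <- unit[, 1] / nrm; y <- unit[, 2] / nrm; z <- unit[, 3] / nrm
  if (frame == "top-z") {
    az <- rad2deg(atan2(y, x))
    el <- rad2deg(asin(clamp(z, -1, 1)))
    # at the dorsal pole the azimuth is degenerate
    az[abs(el) > 90 - 1e-9] <- 0
  } else {
    polar <- rad2deg(acos(clamp(x, -1, 1)))
    s <- ifelse(y < 0, -1, 1)
    az <- s * polar
    el <- rad2deg(atan2(z, abs(y)))
    # at the rostral/caudal pole the elevation is degenerate
    el[abs(sin(deg2rad(polar))) < 1e-12] <- 0
  }
  data.frame(azimuth = az, elevation = el)
}

#' Convert directions between coordinate frames
#'
#' Exact spherical change of the polar axis; a round trip is the identity
#' (up to the documented canonicalization at the poles).
#'
#' @param directions data.frame with `azimuth`, `elevation` columns (degrees).
#' @param from,to frame tags (`"front-z"` or `"top-z"`).
#' @return data.frame with converted `azimuth`, `elevation`.
#' @export
convert_frame <- function(directions, from, to) {
  from <- match.arg(from, c("front-z", "top-z"))
  to <- match.arg(to, c("front-z", "top-z"))
  if (from == to) {
    return(directions[, c("azimuth", "elevation")])
  }
  u <- direction_to_unit(directions$azimuth, directions$elevation, from)
  unit_to_direction(u, to)
}

# Great-circle angular distance in degrees between unit-vector rows.
angular_distance <- function(u, v) {
  if (is.null(dim(u))) u <- matrix(u, nrow = 1)
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  rad2deg(acos(clamp(rowSums(u * v), -1, 1)))
}
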