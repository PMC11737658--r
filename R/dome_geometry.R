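# Dome angular coordinates, engine Cartesian coordinates, and fisheye
# image coordinates.
#
# Axis convention (documented prominently because everything downstream
# depends on it): forward +X, right +Y, up +Z. Dome coordinates are
# azimuth (degrees, positive rightward) and elevation (degrees, positive
# up) at a fixed radius, with (0, 0) the front-center direction of the
# dome. For a subject at the dome center gazing at (0, 0), dome
# coordinates equal visual angles.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Default dome geometry constants
#'
#' The reference dome has a 60 cm radius and extends to 250 degrees of
#' visual field, i.e. a maximum polar angle of 125 degrees from the
#' front-center direction.
#'
#' @export
DOME_RADIUS_CM <- 60

#' @rdname DOME_RADIUS_CM
#' @export
DOME_MAX_POLAR_DEG <- 125

#' Convert dome angular coordinates to Cartesian coordinates
#'
#' @param azimuth degrees, positive rightward.
#' @param elevation degrees, positive up.
#' @param radius radial distance (any length unit; the output inherits it).
#' @return data frame with columns `x` (forward), `y` (right), `z` (up).
#' @examples
#' dome_to_cartesian(0, 0, 60)    # (60, 0, 0): straight ahead
#' dome_to_cartesian(90, 0, 60)   # (0, 60, 0): due right
#' @export
dome_to_cartesian <- function(azimuth, elevation, radius = DOME_RADIUS_CM) {
  if (any(radius <= 0)) stop("radius must be > 0")
  az <- .deg2rad(azimuth); el <- .deg2rad(elevation)
  data.frame(x = radius * cos(el) * cos(az),
             y = radius * cos(el) * sin(az),
             z = radius * sin(el))
}

#' Convert Cartesian coordinates to dome angular coordinates
#'
#' Inverse of [dome_to_cartesian()]: azimuth in (-180, 180], elevation in
#' [-90, 90].
#'
#' @param x,y,z Cartesian coordinates (forward, right, up).
#' @return data frame with columns `azimuth`, `elevation`, `radius`.
#' @export
cartesian_to_dome <- function(x, y, z) {
  r <- sqrt(x^2 + y^2 + z^2)
  if (any(r == 0)) stop("cannot convert the zero vector to dome coordinates")
  el <- .rad2deg(asin(pmin(1, pmax(-1, z / r))))
  az <- .rad2deg(atan2(y, x))
  az[az <= -180] <- az[az <= -180] + 360
  data.frame(azimuth = az, elevation = el, radius = r)
}

#' Polar angle from the front-center direction
#'
#' @param azimuth,elevation dome coordinates in degrees.
#' @return angle in degrees between the direction and the forward axis; a
#'   direction is on the dome surface while this is at most
#'   [DOME_MAX_POLAR_DEG].
#' @export
dome_polar_angle <- function(azimuth, elevation) {
  c_th <- cos(.deg2rad(elevation)) * cos(.deg2rad(azimuth))
  .rad2deg(acos(pmin(1, pmax(-1, c_th))))
}

#' Dome coordinates as visual angles
#'
#' For a subject at the dome center gazing at dome coordinate (0, 0), a
#' stimulus placed at dome coordinates (a, e) subtends visual angles (a, e):
#' the identity is exact by construction of the coordinate system, and this
#' helper exists to make that convention explicit in analysis code.
#'
#' @param azimuth,elevation dome coordinates in degrees.
#' @return data frame with columns `azimuth` and `elevation` (visual angles,
#'   degrees), numerically identical to the input.
#' @export
dome_to_visual_angle <- function(azimuth, elevation) {
  data.frame(azimuth = azimuth, elevation = elevation)
}

# Fisheye --------------------------------------------------------------------

#' Map view directions to fisheye image coordinates
#'
#' Equidistant fisheye model: the polar angle theta from the forward axis
#' maps linearly to radial distance in the image, with the image circle
#' radius 0.5 (in normalized [0,1]^2 coordinates) corresponding to
#' `theta_max`. The forward direction maps to the image center (0.5, 0.5)
#' and the image azimuth (angle around the forward axis) is preserved.
#'
#' @param x,y,z direction (forward, right, up); normalized internally.
#' @param theta_max maximum polar angle (degrees) at the image circle rim.
#' @return data frame with columns `u`, `v` (normalized image coordinates)
#'   and `inside` (whether theta <= theta_max).
#' @export
direction_to_fisheye <- function(x, y, z, theta_max = DOME_MAX_POLAR_DEG) {
  r <- sqrt(x^2 + y^2 + z^2)
  if (any(r == 0)) stop("zero direction")
  x <- x / r; y <- y / r; z <- z / r
  theta <- acos(pmin(1, pmax(-1, x)))
  rad <- 0.5 * .rad2deg(theta) / theta_max
  psi <- atan2(z, y)
  yz <- sqrt(y^2 + z^2)
  # at the exact center psi is undefined; radius is 0 there so any value works
  psi[yz == 0] <- 0
  data.frame(u = 0.5 + rad * cos(psi), v = 0.5 + rad * sin(psi),
             inside = .rad2deg(theta) <= theta_max + 1e-12)
}

# Five-camera rig: 90-degree square frusta facing front, left, right, up,
# down. Each face is (axis, right-in-face, up-in-face); bases are orthonormal
# so projection and reconstruction are exact inverses.
.rig_faces <- list(
  front = list(a = c(1, 0, 0),  r = c(0, 1, 0),  u = c(0, 0, 1)),
  left  = list(a = c(0, -1, 0), r = c(1, 0, 0),  u = c(0, 0, 1)),
  right = list(a = c(0, 1, 0),  r = c(-1, 0, 0), u = c(0, 0, 1)),
  up    = list(a = c(0, 0, 1),  r = c(0, 1, 0),  u = c(-1, 0, 0)),
  down  = list(a = c(0, 0, -1), r = c(0, 1, 0),  u = c(1, 0, 0)))

#' Fisheye coordinates through the five-camera rig
#'
#' Composes the capture path of the dome projection: choose the 90-degree
#' camera face covering the direction, project onto that face's image
#' plane, reconstruct the direction from the face pixel, and map it through
#' the fisheye law. The result agrees with [direction_to_fisheye()] to
#' floating-point precision; the value of the composition is that it
#' exercises the same face-selection and seam geometry as the rendering
#' rig.
#'
#' @param x,y,z direction (forward, right, up); normalized internally.
#' @param theta_max maximum polar angle (degrees) of the fisheye.
#' @return data frame with columns `u`, `v`, `inside`, and `face` (which
#'   camera face covered the direction).
#' @export
rig_compose_fisheye <- function(x, y, z, theta_max = DOME_MAX_POLAR_DEG) {
  r <- sqrt(x^2 + y^2 + z^2)
  if (any(r == 0)) stop("zero direction")
  x <- x / r; y <- y / r; z <- z / r
  n <- length(x)
  u <- v <- numeric(n)
  ins <- logical(n)
  face_nm <- character(n)
  eps <- 1e-9
  M <- vapply(.rig_faces, function(f) f$a, numeric(3)) # 3 x 5 axes
  for (i in seq_len(n)) {
    d <- c(x[i], y[i], z[i])
    dots <- as.numeric(d %*% M)
    ok <- FALSE
    for (j in order(dots, decreasing = TRUE)) {
      if (dots[j] <= 0) break
      f <- .rig_faces[[j]]
      fu <- sum(d * f$r) / dots[j]
      fv <- sum(d * f$u) / dots[j]
      if (abs(fu) <= 1 + eps && abs(fv) <= 1 + eps) {
        # reconstruct the direction from the face pixel and apply the
        # fisheye law, as the mesh warp of that face does
        d2 <- f$a + fu * f$r + fv * f$u
        fe <- direction_to_fisheye(d2[1], d2[2], d2[3], theta_max)
        u[i] <- fe$u; v[i] <- fe$v; ins[i] <- fe$inside
        face_nm[i] <- names(.rig_faces)[j]
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("direction (", signif(x[i], 4), ", ", signif(y[i], 4), ", ",
           signif(z[i], 4), ") falls outside all five camera frusta ",
           "(the rig's rear coverage gap)")
  }
  data.frame(u = u, v = v, inside = ins, face = face_nm)
}
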