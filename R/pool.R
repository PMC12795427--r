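#' Morris water maze pool geometry
#'
#' Geometry container for the maze: a 1 m diameter pool divided into
#' compass quadrants by axis-aligned lines through the pool center, a
#' hidden 8 cm platform, and a wall zone used for thigmotaxis. Coordinates
#' are metres with the pool center at the origin, x pointing east and y
#' pointing north. Quadrants are half-open in angle: NE = [0, 90) degrees,
#' NW = [90, 180), SW = [180, 270), SE = [270, 360).
#'
#' @param pool_radius Pool radius in metres.
#' @param platform_quadrant Compass quadrant holding the platform
#'   ("NE", "SE", "SW", "NW").
#' @param platform_radius Platform radius in metres (8 cm diameter default).
#' @param platform_dist Distance of the platform center from the pool
#'   center (default half the pool radius).
#' @param wall_width Width of the wall (thigmotaxis) zone in metres.
#' @return A `pool_geometry` list with the platform center resolved to
#'   coordinates.
#' @export
pool_geometry <- function(pool_radius = 0.5,
                          platform_quadrant = "NW",
                          platform_radius = 0.04,
                          platform_dist = pool_radius / 2,
                          wall_width = 0.10) {
  check_scalar_num(pool_radius, "pool_radius", lower = 1e-6)
  check_scalar_num(platform_radius, "platform_radius", lower = 0)
  check_scalar_num(platform_dist, "platform_dist", lower = 0)
  check_scalar_num(wall_width, "wall_width", lower = 1e-9)
  if (wall_width >= pool_radius) abort_field("wall_width", "must be < pool radius")
  if (!platform_quadrant %in% c("NE", "SE", "SW", "NW")) {
    abort_field("platform_quadrant", "must be one of NE, SE, SW, NW")
  }
  if (platform_dist + platform_radius > pool_radius) {
    abort_field("platform_dist", "platform must lie fully inside the pool")
  }
  ang <- quadrant_angle(platform_quadrant)
  structure(
    list(
      pool_center = c(0, 0), pool_radius = pool_radius,
      platform_quadrant = platform_quadrant,
      platform_center = platform_dist * c(cos(ang), sin(ang)),
      platform_radius = platform_radius,
      wall_width = wall_width
    ),
    class = "pool_geometry"
  )
}

# centre angle (radians) of a compass quadrant; N = +y, E = +x
quadrant_angle <- function(q) {
  c(NE = 45, NW = 135, SW = 225, SE = 315)[[q]] * pi / 180
}

# quadrant labels for points, half-open angular convention
point_quadrant <- function(x, y) {
  ang <- atan2(y, x) %% (2 * pi)
  c("NE", "NW", "SW", "SE")[findInterval(ang, c(0, pi / 2, pi, 3 * pi / 2))]
}
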