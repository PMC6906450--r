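# Exact 3D primitives: spheres, intersection circles, tori.
# Coordinate frame: spectrometer centre at the origin, beam along +Z, cm.

#' Construct a sphere
#'
#' @param center Numeric length-3, cm.
#' @param radius Positive radius, cm. For a time-of-flight sphere this is the
#'   arrival time multiplied by the speed of light.
#' @return Object of class `pg_sphere`.
#' @export
pg_sphere <- function(center, radius) {
  stopifnot(is.numeric(center), length(center) == 3, all(is.finite(center)),
            is.numeric(radius), length(radius) == 1, is.finite(radius),
            radius > 0)
  structure(list(center = as.numeric(center), radius = as.numeric(radius)),
            class = "pg_sphere")
}

#' Construct a circle in 3D
#'
#' @param center Numeric length-3, cm.
#' @param radius Non-negative radius, cm.
#' @param axis Unit normal of the circle plane.
#' @return Object of class `pg_circle`.
#' @export
pg_circle <- function(center, radius, axis) {
  stopifnot(length(center) == 3, all(is.finite(center)),
            length(radius) == 1, is.finite(radius), radius >= 0,
            length(axis) == 3, all(is.finite(axis)))
  if (abs(.norm3(axis) - 1) > 1e-12) stop("circle axis must be a unit vector")
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 axis = as.numeric(axis)),
            class = "pg_circle")
}

#' Construct a torus
#'
#' The torus is the locus of points at distance `minor_radius` from a spine
#' circle of radius `major_radius` centred at `center` in the plane normal to
#' `axis`.
#'
#' @param center Numeric length-3, cm.
#' @param axis Unit normal of the spine-circle plane.
#' @param major_radius Spine-circle radius R, cm. Must exceed `minor_radius`.
#' @param minor_radius Tube radius r, cm (default 0.3, i.e. 3 mm).
#' @return Object of class `pg_torus`.
#' @export
pg_torus <- function(center, axis, major_radius, minor_radius = 0.3) {
  stopifnot(length(center) == 3, all(is.finite(center)),
            length(axis) == 3, all(is.finite(axis)),
            is.finite(major_radius), is.finite(minor_radius))
  if (abs(.norm3(axis) - 1) > 1e-12) stop("torus axis must be a unit vector")
  if (!(major_radius > minor_radius && minor_radius > 0))
    stop("torus requires major_radius > minor_radius > 0")
  structure(list(center = as.numeric(center), axis = as.numeric(axis),
                 major_radius = as.numeric(major_radius),
                 minor_radius = as.numeric(minor_radius)),
            class = "pg_torus")
}

#' Intersection circle of two spheres
#'
#' For two time-of-flight spheres of one gamma couple, the returned circle is
#' the locus of possible common emission points. Degenerate configurations
#' (concentric, disjoint, one containing the other, or merely tangent) return
#' `NULL`: a zero-radius circle would yield a degenerate torus downstream, so
#' the caller drops the couple.
#'
#' @param s1,s2 Objects of class [pg_sphere()].
#' @return A [pg_circle()] or `NULL`.
#' @export
sphere_sphere_intersection <- function(s1, s2) {
  stopifnot(inherits(s1, "pg_sphere"), inherits(s2, "pg_sphere"))
  u <- s2$center - s1$center
  d <- .norm3(u)
  r1 <- s1$radius
  r2 <- s2$radius
  if (d <= 1e-12) return(NULL)                       # concentric
  if (!(abs(r1 - r2) < d && d < r1 + r2)) return(NULL)  # disjoint/contained/tangent
  u <- u / d
  a <- (d^2 + r1^2 - r2^2) / (2 * d)
  rad2 <- r1^2 - a^2
  if (rad2 <= 0) return(NULL)
  pg_circle(center = s1$center + a * u, radius = sqrt(rad2), axis = u)
}

#' Fatten an intersection circle into a torus
#'
#' The major radius is the intersection-circle radius; the minor radius (tube
#' radius, default 3 mm) absorbs the hit-position and timing uncertainties of
#' the detector system.
#'
#' @param circle A [pg_circle()] (or `NULL`, which propagates).
#' @param minor_radius Tube radius in cm.
#' @return A [pg_torus()] or `NULL` when the circle radius does not exceed the
#'   minor radius (the tube would self-intersect through the axis).
#' @export
build_torus <- function(circle, minor_radius = 0.3) {
  if (is.null(circle)) return(NULL)
  stopifnot(inherits(circle, "pg_circle"))
  if (circle$radius <= minor_radius) return(NULL)
  pg_torus(center = circle$center, axis = circle$axis,
           major_radius = circle$radius, minor_radius = minor_radius)
}

#' Distance from points to a torus surface
#'
#' @param p Numeric length-3 point or an n x 3 matrix of points (cm).
#' @param torus A [pg_torus()].
#' @return Numeric vector of unsigned distances to the surface, cm.
#' @export
point_torus_distance <- function(p, torus) {
  stopifnot(inherits(torus, "pg_torus"))
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  q <- sweep(p, 2, torus$center)
  qa <- as.vector(q %*% torus$axis)
  qp <- sqrt(pmax(rowSums(q * q) - qa^2, 0))
  abs(sqrt((qp - torus$major_radius)^2 + qa^2) - torus$minor_radius)
}

#' Points on a circle
#'
#' @param circle A [pg_circle()].
#' @param theta Angles in radians.
#' @return Matrix of points (length(theta) x 3), cm.
#' @export
circle_points <- function(circle, theta) {
  stopifnot(inherits(circle, "pg_circle"))
  fr <- .frame_from_axis(circle$axis)
  outer(rep(1, length(theta)), circle$center) +
    circle$radius * (cos(theta) %o% fr$e1 + sin(theta) %o% fr$e2)
}
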