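# Geometry of the 16-module LaBr3(Ce) spectrometer and ray/crystal services.
# Crystals are cylinders, 2" (5.08 cm) long and 1.5" (3.81 cm) in diameter,
# face-on to the origin: a ring of eight in the transverse plane plus rings of
# four at forward and backward 45 degrees to the beam (+Z) axis.

#' Build the 16-module spectrometer
#'
#' All face centres lie at distance `R_spec` from the origin and every crystal
#' axis passes through the origin, the crystal extending away from it.
#' Ring A: 8 modules at polar angle 90 degrees, azimuths 0, 45, ..., 315.
#' Ring B: 4 modules at polar 45 degrees (forward), azimuths 0, 90, 180, 270.
#' Ring C: 4 modules at polar 135 degrees (backward), same azimuths.
#'
#' @param R_spec Internal radius (source to front face), cm; >= 5.
#' @param crystal_length Crystal length, cm (default 5.08 = 2 inches).
#' @param crystal_radius Crystal radius, cm (default 1.905 = 0.75 inches).
#' @return Object of class `pg_spectrometer`: list with `R_spec`, matrices
#'   `centres` and `axes` (16 x 3; axes point outward from the origin),
#'   `crystal_length`, `crystal_radius`, and `modules` (list of per-module
#'   descriptors with fields `id`, `face_centre`, `axis`, `length`, `radius`).
#' @export
build_spectrometer <- function(R_spec = 8, crystal_length = 5.08,
                               crystal_radius = 1.905) {
  stopifnot(R_spec >= 5, crystal_length > 0, crystal_radius > 0)
  polar <- c(rep(90, 8), rep(45, 4), rep(135, 4)) * pi / 180
  azim <- c(seq(0, 315, by = 45), seq(0, 270, by = 90),
            seq(0, 270, by = 90)) * pi / 180
  dirs <- cbind(sin(polar) * cos(azim), sin(polar) * sin(azim), cos(polar))
  centres <- R_spec * dirs

  # conservative overlap check: distance between crystal axis segments must
  # exceed the crystal diameter
  seg_a <- centres
  seg_b <- centres + crystal_length * dirs
  for (i in 1:15) for (j in (i + 1):16) {
    d <- .segment_segment_distance(seg_a[i, ], seg_b[i, ], seg_a[j, ], seg_b[j, ])
    if (d < 2 * crystal_radius)
      stop(sprintf("crystals %d and %d overlap at R_spec = %g cm", i - 1, j - 1,
                   R_spec))
  }

  modules <- lapply(1:16, function(k) {
    list(id = k - 1L, face_centre = centres[k, ], axis = dirs[k, ],
         length = crystal_length, radius = crystal_radius)
  })
  structure(list(R_spec = R_spec, centres = centres, axes = dirs,
                 crystal_length = crystal_length,
                 crystal_radius = crystal_radius, modules = modules),
            class = "pg_spectrometer")
}

.segment_segment_distance <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  cpar <- sum(d1 * r); b <- sum(d1 * d2)
  denom <- a * e - b * b
  s <- if (denom > 1e-12) max(0, min(1, (b * f - cpar * e) / denom)) else 0
  t <- (b * s + f) / e
  if (t < 0) { t <- 0; s <- max(0, min(1, -cpar / a)) }
  if (t > 1) { t <- 1; s <- max(0, min(1, (b - cpar) / a)) }
  .norm3((p1 + s * d1) - (p2 + t * d2))
}

## vectorised ray vs finite-cylinder intersection: O (n x 3) origins,
## D (n x 3) unit directions; returns cbind(t_in, t_out) with Inf for misses
.ray_cylinder <- function(O, D, centre, axis, len, rho, tol = 1e-9) {
  n <- nrow(O)
  oc <- sweep(O, 2, centre)
  oa <- as.vector(oc %*% axis)
  da <- as.vector(D %*% axis)
  op <- oc - outer(oa, axis)
  dp <- D - outer(da, axis)
  A <- rowSums(dp * dp)
  B <- 2 * rowSums(op * dp)
  C <- rowSums(op * op) - rho^2

  t_in <- rep(Inf, n); t_out <- rep(-Inf, n)
  consider <- function(t, ok) {
    ok <- ok & is.finite(t) & t >= -tol
    t[t < 0] <- 0
    t_in <<- ifelse(ok & t < t_in, t, t_in)
    t_out <<- ifelse(ok & t > t_out, t, t_out)
  }

  disc <- B * B - 4 * A * C
  has <- disc >= 0 & A > 1e-300
  sq <- sqrt(pmax(disc, 0))
  for (sgn in c(-1, 1)) {
    t <- (-B + sgn * sq) / (2 * A)
    ax_ok <- { z <- oa + t * da; z >= -tol & z <= len + tol }
    consider(t, has & ax_ok)
  }
  for (zcap in c(0, len)) {
    t <- (zcap - oa) / da
    p <- op + t * dp
    rad_ok <- rowSums(p * p) <= rho^2 + tol
    consider(t, abs(da) > 1e-300 & rad_ok)
  }
  # ray starting inside the crystal enters at t = 0
  inside0 <- oa >= -tol & oa <= len + tol & rowSums(op * op) <= rho^2 + tol
  t_in[inside0] <- 0
  t_out[!is.finite(t_in)] <- Inf
  cbind(t_in = t_in, t_out = t_out)
}

#' Ray entry and exit points of a detector crystal
#'
#' Analytic intersection of a ray with the finite cylinder of one module
#' (lateral surface and both caps).
#'
#' @param origin Ray origin, cm.
#' @param direction Unit direction.
#' @param det A module descriptor from [build_spectrometer()] (`modules[[k]]`).
#' @return `NULL` on a miss, otherwise list with `entry`, `exit` (points, cm)
#'   and `t_entry`, `t_exit` (ray parameters, cm).
#' @export
ray_crystal_entry <- function(origin, direction, det) {
  stopifnot(length(origin) == 3, length(direction) == 3)
  if (abs(.norm3(direction) - 1) > 1e-9)
    stop("direction must be a unit vector")
  tt <- .ray_cylinder(matrix(origin, 1), matrix(direction, 1),
                      det$face_centre, det$axis, det$length, det$radius)
  if (!is.finite(tt[1, 1])) return(NULL)
  list(entry = origin + tt[1, 1] * direction,
       exit = origin + tt[1, 2] * direction,
       t_entry = unname(tt[1, 1]), t_exit = unname(tt[1, 2]))
}

## first crystal entered for each ray; returns det index (NA on miss) and
## entry/exit ray parameters
.trace_rays <- function(O, D, spec) {
  n <- nrow(O)
  best_t <- rep(Inf, n); best_det <- rep(NA_integer_, n); best_out <- rep(Inf, n)
  for (k in 1:16) {
    tt <- .ray_cylinder(O, D, spec$centres[k, ], spec$axes[k, ],
                        spec$crystal_length, spec$crystal_radius)
    better <- tt[, 1] < best_t
    best_t[better] <- tt[better, 1]
    best_out[better] <- tt[better, 2]
    best_det[better] <- k
  }
  list(det = best_det, t_entry = best_t, t_exit = best_out)
}

#' Monte-Carlo solid-angle fraction of the spectrometer
#'
#' Fraction of isotropic emission directions from `point` whose ray enters any
#' crystal, with its binomial standard error.
#'
#' @param spec A [build_spectrometer()] object.
#' @param point Emission point, cm (default the origin).
#' @param n_samples Number of sampled directions (>= 1e4).
#' @param seed Optional integer seed.
#' @return List with `fraction`, `se` and `n`.
#' @export
solid_angle_fraction <- function(spec, point = c(0, 0, 0), n_samples = 1e5,
                                 seed = NULL) {
  stopifnot(inherits(spec, "pg_spectrometer"), n_samples >= 1e4)
  if (!is.null(seed)) set.seed(seed)
  D <- .isotropic_directions(n_samples)
  O <- matrix(rep(point, each = n_samples), ncol = 3)
  hit <- !is.na(.trace_rays(O, D, spec)$det)
  p <- mean(hit)
  list(fraction = p, se = sqrt(p * (1 - p) / n_samples), n = n_samples)
}

.isotropic_directions <- function(n) {
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(1 - z^2, 0))
  cbind(s * cos(phi), s * sin(phi), z)
}

## point-in-crystal test (vectorised over rows of P)
.in_crystal <- function(P, centre, axis, len, rho, tol = 1e-9) {
  q <- sweep(P, 2, centre)
  a <- as.vector(q %*% axis)
  r2 <- rowSums(q * q) - a^2
  a >= -tol & a <= len + tol & r2 <= rho^2 + tol
}

#' @export
print.pg_spectrometer <- function(x, ...) {
  cat(sprintf("LaBr3(Ce) spectrometer: 16 modules, internal radius %.4g cm\n",
              x$R_spec))
  cat(sprintf("  crystals %.3g cm long, %.3g cm radius, face-on to origin\n",
              x$crystal_length, x$crystal_radius))
  invisible(x)
}
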