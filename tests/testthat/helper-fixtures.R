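# Shared fixtures: a brute-force triangle/triangle oracle (all six
# edge-vs-triangle clips plus coplanar containment) kept independent of the
# compiled interval test, and factories for noise-free gamma couples.

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.point_in_tri3 <- function(p, tri, tol = 1e-10) {
  v0 <- tri[2, ] - tri[1, ]
  v1 <- tri[3, ] - tri[1, ]
  v2 <- p - tri[1, ]
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  if (abs(den) < 1e-300) return(FALSE)
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  v >= -tol && w >= -tol && (1 - v - w) >= -tol
}

.point_in_tri2 <- function(px, py, tx, ty, tol = 1e-12) {
  o <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d1 <- o(tx[1], ty[1], tx[2], ty[2], px, py)
  d2 <- o(tx[2], ty[2], tx[3], ty[3], px, py)
  d3 <- o(tx[3], ty[3], tx[1], ty[1], px, py)
  !((d1 < -tol || d2 < -tol || d3 < -tol) && (d1 > tol || d2 > tol || d3 > tol))
}

.seg_seg_cross2 <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  o <- function(px, py, qx, qy, rx, ry) (qx - px) * (ry - py) - (qy - py) * (rx - px)
  d1 <- o(cx, cy, dx, dy, ax, ay); d2 <- o(cx, cy, dx, dy, bx, by)
  d3 <- o(ax, ay, bx, by, cx, cy); d4 <- o(ax, ay, bx, by, dx, dy)
  ((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))
}

## coplanar segment vs triangle, projected to the plane's dominant axes
.coplanar_seg_tri <- function(a, b, tri, n) {
  drop <- which.max(abs(n))
  keep <- setdiff(1:3, drop)
  ax <- a[keep[1]]; ay <- a[keep[2]]
  bx <- b[keep[1]]; by <- b[keep[2]]
  tx <- tri[, keep[1]]; ty <- tri[, keep[2]]
  if (.point_in_tri2(ax, ay, tx, ty) || .point_in_tri2(bx, by, tx, ty))
    return(TRUE)
  for (i in 1:3) {
    j <- i %% 3 + 1
    if (.seg_seg_cross2(ax, ay, bx, by, tx[i], ty[i], tx[j], ty[j]))
      return(TRUE)
  }
  FALSE
}

.seg_tri_hits <- function(a, b, tri, n) {
  da <- sum(n * (a - tri[1, ]))
  db <- sum(n * (b - tri[1, ]))
  scale <- sqrt(sum(n * n)) *
    max(sqrt(sum((a - tri[1, ])^2)), sqrt(sum((b - tri[1, ])^2)), 1)
  eps <- 1e-12 * scale
  if (abs(da) <= eps && abs(db) <= eps)
    return(.coplanar_seg_tri(a, b, tri, n))
  if ((da > eps && db > eps) || (da < -eps && db < -eps)) return(FALSE)
  if (abs(da - db) < 1e-300) return(FALSE)
  t <- min(max(da / (da - db), 0), 1)
  .point_in_tri3(a + t * (b - a), tri)
}

## brute-force boolean triangle/triangle intersection
oracle_tri_tri <- function(t1, t2) {
  n1 <- .cross(t1[2, ] - t1[1, ], t1[3, ] - t1[1, ])
  n2 <- .cross(t2[2, ] - t2[1, ], t2[3, ] - t2[1, ])
  for (i in 1:3) {
    j <- i %% 3 + 1
    if (.seg_tri_hits(t1[i, ], t1[j, ], t2, n2)) return(TRUE)
    if (.seg_tri_hits(t2[i, ], t2[j, ], t1, n1)) return(TRUE)
  }
  FALSE
}

## a noise-free gamma couple around emission point p0: two hit points at
## random distances, exact flight radii; returns sphere pair and the torus
make_noise_free_couple <- function(p0, rmin = 8, rmax = 12, minor = 0.3) {
  repeat {
    d1 <- pgrange:::.isotropic_directions(1)[1, ]
    d2 <- pgrange:::.isotropic_directions(1)[1, ]
    h1 <- p0 + runif(1, rmin, rmax) * d1
    h2 <- p0 + runif(1, rmin, rmax) * d2
    s1 <- pg_sphere(h1, sqrt(sum((h1 - p0)^2)))
    s2 <- pg_sphere(h2, sqrt(sum((h2 - p0)^2)))
    circ <- sphere_sphere_intersection(s1, s2)
    tor <- build_torus(circ, minor)
    if (!is.null(tor))
      return(list(s1 = s1, s2 = s2, circle = circ, torus = tor))
  }
}

make_noise_free_torus <- function(p0, ...) make_noise_free_couple(p0, ...)$torus

## distance from a point to a circle in 3D
point_circle_distance <- function(p, circle) {
  q <- p - circle$center
  qa <- sum(q * circle$axis)
  qp <- sqrt(max(sum(q * q) - qa^2, 0))
  sqrt((qp - circle$radius)^2 + qa^2)
}

## noise-free pipeline configuration for point-source tests
point_source_config <- function(source, n_couples, seed = 1L, ...) {
  pg_config(source = source, n_couples = as.integer(n_couples), seed = seed,
            hit_sigma = 0, energy_res_fwhm = 0, timing_sigma = 0, p_fe = 1,
            ...)
}
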