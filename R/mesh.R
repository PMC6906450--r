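# Torus surface triangulation, clipping to the reconstruction region, and the
# mesh-based torus-torus intersection surface machinery.

#' Spherical reconstruction region
#'
#' The central volume of the spectrometer, realised as the ball of radius
#' `radius` centred at the origin (the maximal symmetric volume bounded by the
#' detector faces). Torus sections outside it are discarded before the
#' pairwise intersection step.
#'
#' @param radius Region radius in cm, normally the spectrometer internal
#'   radius.
#' @return Object of class `pg_region`.
#' @export
pg_region <- function(radius) {
  stopifnot(is.finite(radius), radius > 0)
  structure(list(radius = as.numeric(radius)), class = "pg_region")
}

#' Triangulate a torus surface
#'
#' Parametric grid x(u,v) = c + (R + r cos v)(cos u e1 + sin u e2) + r sin v n
#' with u_i = 2*pi*i/n_u, v_j = 2*pi*j/n_v; each quad is split into two
#' triangles, giving a closed mesh of n_u*n_v vertices and 2*n_u*n_v
#' triangles, every vertex exactly on the surface.
#'
#' @param torus A [pg_torus()].
#' @param n_u Number of subdivisions around the spine circle (>= 8).
#' @param n_v Number of subdivisions around the tube (>= 6).
#' @return Object of class `pg_mesh`: list with `vertices` (n x 3),
#'   `triangles` (m x 3, 1-based), the generating `torus`, and `max_edge`,
#'   the longest edge length (used for conservative broad-phase margins).
#' @export
triangulate_torus <- function(torus, n_u = 240, n_v = 24) {
  stopifnot(inherits(torus, "pg_torus"))
  stopifnot(n_u >= 8, n_v >= 6)
  fr <- .frame_from_axis(torus$axis)
  u <- 2 * pi * (0:(n_u - 1)) / n_u
  v <- 2 * pi * (0:(n_v - 1)) / n_v
  uu <- rep(u, each = n_v)
  vv <- rep(v, times = n_u)
  ring <- torus$major_radius + torus$minor_radius * cos(vv)
  verts <- outer(rep(1, n_u * n_v), torus$center) +
    (ring * cos(uu)) %o% fr$e1 +
    (ring * sin(uu)) %o% fr$e2 +
    (torus$minor_radius * sin(vv)) %o% torus$axis

  idx <- function(i, j) (i %% n_u) * n_v + (j %% n_v) + 1L
  i <- rep(0:(n_u - 1), each = n_v)
  j <- rep(0:(n_v - 1), times = n_u)
  a <- idx(i, j); b <- idx(i + 1, j); cc <- idx(i + 1, j + 1); d <- idx(i, j + 1)
  tris <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  storage.mode(tris) <- "integer"

  e1l <- sqrt(rowSums((verts[tris[, 1], , drop = FALSE] - verts[tris[, 2], , drop = FALSE])^2))
  e2l <- sqrt(rowSums((verts[tris[, 2], , drop = FALSE] - verts[tris[, 3], , drop = FALSE])^2))
  e3l <- sqrt(rowSums((verts[tris[, 3], , drop = FALSE] - verts[tris[, 1], , drop = FALSE])^2))
  structure(list(vertices = verts, triangles = tris, torus = torus,
                 max_edge = max(e1l, e2l, e3l)),
            class = "pg_mesh")
}

#' Clip a mesh to the reconstruction region
#'
#' Keeps triangles with at least one vertex inside the region; the result may
#' be an open mesh, or empty when the torus lies entirely outside the
#' spectrometer central volume (such a torus contributes nothing).
#'
#' @param mesh A `pg_mesh`.
#' @param region A [pg_region()].
#' @return A clipped `pg_mesh` (possibly with zero triangles).
#' @export
clip_mesh_to_region <- function(mesh, region) {
  stopifnot(inherits(mesh, "pg_mesh"), inherits(region, "pg_region"))
  if (nrow(mesh$triangles) == 0) return(mesh)
  inside <- rowSums(mesh$vertices^2) <= region$radius^2
  keep <- inside[mesh$triangles[, 1]] | inside[mesh$triangles[, 2]] |
    inside[mesh$triangles[, 3]]
  tris <- mesh$triangles[keep, , drop = FALSE]
  used <- sort(unique(as.vector(tris)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  tris[] <- remap[tris]
  storage.mode(tris) <- "integer"
  structure(list(vertices = mesh$vertices[used, , drop = FALSE],
                 triangles = tris, torus = mesh$torus,
                 max_edge = mesh$max_edge),
            class = "pg_mesh")
}

#' Triangle/triangle intersection test
#'
#' Interval-overlap (Moller) test. Non-coplanar intersecting triangles return
#' the 3D intersection segment (zero-length for a touching contact). Coplanar
#' overlapping pairs are detected by 2D edge/containment tests and flagged,
#' but carry no segment geometry (a measure-zero configuration under
#' floating-point meshes; such contributions are dropped from centroid
#' accumulation).
#'
#' @param t1,t2 3 x 3 matrices, one vertex per row (cm). Triangles must be
#'   non-degenerate (area > 1e-12 cm^2).
#' @return `NULL` when disjoint; otherwise a list with `segment` (2 x 3 matrix
#'   of endpoints, or `NULL` for coplanar contact) and logical `coplanar`.
#' @export
tri_tri_intersect <- function(t1, t2) {
  t1 <- as.matrix(t1); t2 <- as.matrix(t2)
  stopifnot(all(dim(t1) == c(3, 3)), all(dim(t2) == c(3, 3)))
  res <- cpp_tri_tri(t1, t2)
  if (!res$hit) return(NULL)
  list(segment = res$segment, coplanar = res$coplanar)
}

#' Intersection components of two torus meshes
#'
#' Broad-phase pruning (whole-mesh bounds, an analytic band filter against the
#' partner torus surface, per-triangle bounding boxes) followed by the
#' triangle/triangle test over surviving pairs. All positive-length
#' intersection segments are clustered into connected components (segments
#' linked when endpoints fall within `cluster_eps`), and each component is
#' summarised by the length-weighted centroid of its segment midpoints.
#'
#' An empty component list marks a "NaN" pair in the reconstruction
#' bookkeeping. Identical or near-identical meshes (bounds equal within 1e-9)
#' are skipped with a warning and yield an empty list.
#'
#' @param m1,m2 Clipped `pg_mesh` objects.
#' @param cluster_eps Endpoint-linking tolerance in cm (default 0.1, i.e.
#'   1 mm).
#' @return List of components, each a list with `centroid` (length-3),
#'   `length` (total curve length, cm) and `n_segments`. Attributes
#'   `n_segments`, `n_hits` and `n_coplanar` carry pair-level counts.
#' @export
torus_pair_intersection_positions <- function(m1, m2, cluster_eps = 0.1) {
  stopifnot(inherits(m1, "pg_mesh"), inherits(m2, "pg_mesh"))
  res <- .pair_components(m1, m2, cluster_eps)
  if (isTRUE(res$identical)) {
    warning("identical or near-identical torus meshes skipped")
    return(structure(list(), n_segments = 0L, n_hits = 0L, n_coplanar = 0L))
  }
  k <- nrow(res$centroids)
  comps <- lapply(seq_len(k), function(i) {
    list(centroid = res$centroids[i, ], length = res$lengths[i],
         n_segments = res$comp_nseg[i])
  })
  structure(comps, n_segments = res$n_segments, n_hits = res$n_hits,
            n_coplanar = res$n_coplanar)
}

.torus_vec <- function(torus) {
  if (is.null(torus)) return(numeric(0))
  c(torus$center, torus$axis, torus$major_radius, torus$minor_radius)
}

## conservative band margin: any point of a triangle lies within max_edge of
## each of its vertices, and partner mesh triangles sag below the exact torus
## surface by far less than 0.1 cm at the resolutions used
.pair_components <- function(m1, m2, cluster_eps) {
  margin1 <- m1$max_edge + 0.1
  margin2 <- m2$max_edge + 0.1
  cpp_pair_components(m1$vertices, m1$triangles, .torus_vec(m1$torus),
                      m2$vertices, m2$triangles, .torus_vec(m2$torus),
                      margin1, margin2, cluster_eps)
}

#' @export
print.pg_mesh <- function(x, ...) {
  cat("torus surface mesh:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles\n")
  if (!is.null(x$torus))
    cat(sprintf("  torus R = %.3f cm, r = %.3f cm\n",
                x$torus$major_radius, x$torus$minor_radius))
  invisible(x)
}
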