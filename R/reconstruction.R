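# The three-stage reconstruction: coincident couple selection by energy
# windows, time-of-flight sphere intersection and torus construction per
# couple, and all-pairs torus intersection into virtual emission positions.

#' Energy windows for couple selection
#'
#' The base windows are centred on the two cascade energies with extents
#' reflecting the 3% FWHM detector resolution: 2.659-2.823 MeV for the low
#' line and 5.946-6.321 MeV for the high line. With `escape_peaks = TRUE`,
#' single- and double-escape windows (centres shifted by 0.511 and 1.022 MeV,
#' same fractional half-widths) are added to each group.
#'
#' @param escape_peaks Logical; add escape-peak acceptance windows.
#' @return Object of class `pg_windows`: data.frame with `label`, `lo`, `hi`
#'   (MeV) and `group` ("low"/"high").
#' @export
energy_windows <- function(escape_peaks = FALSE) {
  win <- data.frame(label = c("2.741", "6.128"),
                    lo = c(2.659, 5.946), hi = c(2.823, 6.321),
                    group = c("low", "high"), stringsAsFactors = FALSE)
  if (escape_peaks) {
    centre <- c(2.741, 6.128)
    frac <- (win$hi - win$lo) / 2 / centre
    esc <- do.call(rbind, lapply(1:2, function(i) {
      ce <- centre[i] - c(0.511, 1.022)
      hw <- frac[i] * ce
      data.frame(label = paste0(win$label[i], c("-se", "-de")),
                 lo = ce - hw, hi = ce + hw, group = win$group[i],
                 stringsAsFactors = FALSE)
    }))
    win <- rbind(win, esc)
  }
  o <- order(win$lo)
  if (any(win$lo[o][-1] < win$hi[o][-nrow(win)]))
    stop("energy windows overlap")
  structure(win, class = c("pg_windows", "data.frame"))
}

## "low" / "high" / NA for each energy (inclusive bounds)
.classify_energy <- function(E, windows) {
  out <- rep(NA_character_, length(E))
  for (i in seq_len(nrow(windows))) {
    sel <- E >= windows$lo[i] & E <= windows$hi[i]
    out[sel] <- windows$group[i]
  }
  out
}

#' Select coincident gamma couples (stage 1)
#'
#' Events are grouped by bunch (`event_id`, the per-primary structure of the
#' event stream) and, within a bunch, by a sliding coincidence time window. A
#' couple is emitted when exactly two events fall in the window, come from
#' different detectors, and their energies fall one in each group of windows
#' (inclusive bounds, irrespective of order). Windows holding three or more
#' events are rejected entirely, and every event is consumed by at most one
#' couple. All other events are rejected.
#'
#' @param events Event table (columns `event_id, det, E_MeV, t_ns, x_cm, y_cm,
#'   z_cm`), time-sorted or not.
#' @param windows An [energy_windows()] object.
#' @param cfg A [pg_config()] (uses `coincidence_window`, ns).
#' @return `data.frame` with one row per couple: event 1 fields (`det1, E1,
#'   t1, x1, y1, z1`), event 2 fields likewise, and `event_id`. Event 1 is the
#'   earlier event. Attribute `counts` reports the attrition bookkeeping.
#' @export
select_couples <- function(events, windows = energy_windows(),
                           cfg = pg_config()) {
  need <- c("event_id", "det", "E_MeV", "t_ns", "x_cm", "y_cm", "z_cm")
  if (!all(need %in% names(events)))
    stop("event table lacks columns: ",
         paste(setdiff(need, names(events)), collapse = ", "))
  empty <- data.frame(det1 = integer(), E1 = numeric(), t1 = numeric(),
                      x1 = numeric(), y1 = numeric(), z1 = numeric(),
                      det2 = integer(), E2 = numeric(), t2 = numeric(),
                      x2 = numeric(), y2 = numeric(), z2 = numeric(),
                      event_id = integer())
  if (nrow(events) == 0)
    return(structure(empty, counts = list(n_events = 0L, n_windows = 0L,
                                          n_couples = 0L, n_rejected_multi = 0L)))
  o <- order(events$event_id, events$t_ns)
  ev <- events[o, , drop = FALSE]
  new_bunch <- c(TRUE, diff(ev$event_id) != 0)
  gap <- c(Inf, diff(ev$t_ns))
  grp <- cumsum(new_bunch | gap > cfg$coincidence_window)
  sizes <- tabulate(grp)
  n_multi <- sum(sizes >= 3)
  two <- which(sizes == 2L)
  if (length(two) == 0)
    return(structure(empty, counts = list(n_events = nrow(events),
                                          n_windows = length(sizes),
                                          n_couples = 0L,
                                          n_rejected_multi = n_multi)))
  first <- match(two, grp)          # groups are contiguous in ev
  second <- first + 1L
  grp_class1 <- .classify_energy(ev$E_MeV[first], windows)
  grp_class2 <- .classify_energy(ev$E_MeV[second], windows)
  ok <- ev$det[first] != ev$det[second] &
    !is.na(grp_class1) & !is.na(grp_class2) &
    ((grp_class1 == "low" & grp_class2 == "high") |
       (grp_class1 == "high" & grp_class2 == "low"))
  f <- first[ok]; s <- second[ok]
  out <- data.frame(det1 = ev$det[f], E1 = ev$E_MeV[f], t1 = ev$t_ns[f],
                    x1 = ev$x_cm[f], y1 = ev$y_cm[f], z1 = ev$z_cm[f],
                    det2 = ev$det[s], E2 = ev$E_MeV[s], t2 = ev$t_ns[s],
                    x2 = ev$x_cm[s], y2 = ev$y_cm[s], z2 = ev$z_cm[s],
                    event_id = ev$event_id[f])
  rownames(out) <- NULL
  structure(out, counts = list(n_events = nrow(events),
                               n_windows = length(sizes),
                               n_couples = nrow(out),
                               n_rejected_multi = n_multi))
}

#' Convert one couple into its torus (stage 2)
#'
#' Two spheres are built, centred on the recorded hit coordinates with radii
#' r = t * c; their intersection circle is fattened into a torus with the
#' configured tube radius. Degenerate configurations (non-intersecting
#' spheres, circle radius at or below the tube radius) return `NULL` and the
#' couple is dropped.
#'
#' @param couple One row of the [select_couples()] output.
#' @param cfg A [pg_config()] (uses `minor_radius`).
#' @return A [pg_torus()] or `NULL`.
#' @export
couple_to_torus <- function(couple, cfg = pg_config()) {
  s1 <- pg_sphere(c(couple$x1, couple$y1, couple$z1), couple$t1 * C_LIGHT)
  s2 <- pg_sphere(c(couple$x2, couple$y2, couple$z2), couple$t2 * C_LIGHT)
  build_torus(sphere_sphere_intersection(s1, s2), cfg$minor_radius)
}

#' Convert all couples into tori
#'
#' @param couples Output of [select_couples()].
#' @param cfg A [pg_config()].
#' @return List of [pg_torus()] objects; attribute `n_dropped` counts couples
#'   lost to degenerate sphere configurations.
#' @export
couples_to_tori <- function(couples, cfg = pg_config()) {
  tori <- lapply(seq_len(nrow(couples)), function(i)
    couple_to_torus(couples[i, , drop = FALSE], cfg))
  dropped <- sum(vapply(tori, is.null, logical(1)))
  structure(Filter(Negate(is.null), tori), n_dropped = dropped)
}

#' Reconstruct virtual emission positions (stage 3)
#'
#' Each torus is triangulated once and clipped to the spectrometer central
#' volume; all n(n-1)/2 torus pairs are then intersected and every
#' intersection-component centroid inside the region is stored as a virtual
#' emission position. Bookkeeping follows the couple-analysis convention: `n`
#' tori, `n_nan` null pairs, `n_positions` stored centroids, and the nominal
#' count `2 * n - n_nan` reported alongside (not enforced).
#'
#' @param tori List of [pg_torus()] objects (e.g. from [couples_to_tori()]).
#' @param cfg A [pg_config()] (mesh resolution, clustering tolerance, region
#'   radius `R_spec`).
#' @return Object of class `pg_vps`: list with `positions` (matrix, one
#'   centroid per row), `n`, `n_pairs`, `n_nan`, `n_positions`,
#'   `eq_nominal_positions`, `n_outside_region`, `n_identical_skipped`.
#' @export
reconstruct_virtual_positions <- function(tori, cfg = pg_config()) {
  n <- length(tori)
  region <- pg_region(cfg$R_spec)
  out <- list(positions = matrix(numeric(0), 0, 3,
                                 dimnames = list(NULL, c("x", "y", "z"))),
              n = n, n_pairs = 0L, n_nan = 0L, n_positions = 0L,
              eq_nominal_positions = 2L * n, n_outside_region = 0L,
              n_identical_skipped = 0L)
  class(out) <- "pg_vps"
  if (n < 2) return(out)

  meshes <- lapply(tori, function(tor)
    clip_mesh_to_region(triangulate_torus(tor, cfg$n_u, cfg$n_v), region))
  r2 <- cfg$R_spec^2

  pos <- vector("list", 256)
  npos <- 0L
  n_nan <- 0L
  n_outside <- 0L
  n_ident <- 0L
  n_pairs <- 0L
  for (i in seq_len(n - 1)) {
    mi <- meshes[[i]]
    for (j in seq.int(i + 1, n)) {
      n_pairs <- n_pairs + 1L
      mj <- meshes[[j]]
      if (nrow(mi$triangles) == 0 || nrow(mj$triangles) == 0) {
        n_nan <- n_nan + 1L
        next
      }
      res <- .pair_components(mi, mj, cfg$cluster_eps)
      if (isTRUE(res$identical)) {
        n_ident <- n_ident + 1L
        n_nan <- n_nan + 1L
        next
      }
      k <- nrow(res$centroids)
      if (k == 0) {
        n_nan <- n_nan + 1L
        next
      }
      inside <- rowSums(res$centroids^2) <= r2
      n_outside <- n_outside + sum(!inside)
      if (any(inside)) {
        npos <- npos + 1L
        if (npos > length(pos)) pos <- c(pos, vector("list", length(pos)))
        pos[[npos]] <- res$centroids[inside, , drop = FALSE]
      }
    }
  }
  if (n_ident > 0)
    warning(n_ident, " identical torus pair(s) skipped and counted as null")
  positions <- if (npos > 0) do.call(rbind, pos[seq_len(npos)]) else
    matrix(numeric(0), 0, 3)
  colnames(positions) <- c("x", "y", "z")
  out$positions <- positions
  out$n_pairs <- n_pairs
  out$n_nan <- n_nan
  out$n_positions <- nrow(positions)
  out$eq_nominal_positions <- 2L * n - n_nan
  out$n_outside_region <- n_outside
  out$n_identical_skipped <- n_ident
  out
}

#' @export
print.pg_vps <- function(x, ...) {
  cat(sprintf("virtual emission positions: n = %d tori, %d pairs, %d null pairs\n",
              x$n, x$n_pairs, x$n_nan))
  cat(sprintf("  %d positions stored (nominal 2n - N_NaN = %d)\n",
              x$n_positions, x$eq_nominal_positions))
  invisible(x)
}

#' Histogram virtual positions into voxels
#'
#' Half-open binning `[lo, hi)` on each axis; positions outside the bounds are
#' dropped and counted.
#'
#' @param vps A `pg_vps` object or an n x 3 position matrix.
#' @param voxel Voxel edge, cm (default 0.1, i.e. 1 mm).
#' @param bounds List with `x`, `y`, `z` ranges (cm); default the phantom box
#'   of `cfg` in the spectrometer frame.
#' @param cfg A [pg_config()], used only for default bounds.
#' @return Object of class `pg_hist3`: list with `counts` (3D array), `mids`
#'   (bin centres per axis), `breaks`, `voxel`, `n_dropped`.
#' @export
histogram_positions <- function(vps, voxel = 0.1, bounds = NULL,
                                cfg = pg_config()) {
  stopifnot(voxel > 0)
  P <- if (inherits(vps, "pg_vps")) vps$positions else as.matrix(vps)
  if (is.null(bounds)) bounds <- phantom_bounds(cfg)
  brk <- lapply(bounds, function(b) seq(b[1], b[2], by = voxel))
  nb <- vapply(brk, function(b) length(b) - 1L, integer(1))
  ix <- floor((P[, 1] - bounds$x[1]) / voxel) + 1
  iy <- floor((P[, 2] - bounds$y[1]) / voxel) + 1
  iz <- floor((P[, 3] - bounds$z[1]) / voxel) + 1
  ok <- ix >= 1 & ix <= nb[1] & iy >= 1 & iy <= nb[2] & iz >= 1 & iz <= nb[3]
  lin <- (iz[ok] - 1) * nb[1] * nb[2] + (iy[ok] - 1) * nb[1] + ix[ok]
  counts <- array(tabulate(lin, nbins = prod(nb)), dim = nb)
  mids <- lapply(brk, function(b) (b[-1] + b[-length(b)]) / 2)
  structure(list(counts = counts, mids = mids, breaks = brk, voxel = voxel,
                 n_dropped = sum(!ok)),
            class = "pg_hist3")
}

#' Axis marginal of a 3D position histogram
#'
#' @param hist A `pg_hist3` object.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return `data.frame` with `center` (cm) and `count`.
#' @export
hist_marginal <- function(hist, axis = c("z", "x", "y")) {
  stopifnot(inherits(hist, "pg_hist3"))
  axis <- match.arg(axis)
  k <- match(axis, c("x", "y", "z"))
  data.frame(center = hist$mids[[k]],
             count = as.vector(apply(hist$counts, k, sum)))
}

#' @export
print.pg_hist3 <- function(x, ...) {
  cat(sprintf("3D position histogram: %s voxels of %.3g cm, %d counts (%d dropped)\n",
              paste(dim(x$counts), collapse = " x "), x$voxel,
              sum(x$counts), x$n_dropped))
  invisible(x)
}
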