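# Synthetic event generator: samples prompt-gamma couple emissions along the
# beam, transports both gammas to the spectrometer, applies the detector
# response, and emits the event table plus a truth sidecar. A seeded
# Monte-Carlo stand-in for a full transport simulation: only the downstream
# geometry and statistics matter for the reconstruction algorithm.

#' Sample prompt-gamma couple emission points
#'
#' Depth is drawn from the cross-section-weighted emission profile (inverse
#' CDF on a 0.01 cm grid), lateral coordinates from the Gaussian pencil-beam
#' spread. The two gammas of a couple share position and emission time (the
#' ~25 ps cascade delay is far below any detector resolution, so emission time
#' is 0 within each couple's bunch clock). If `cfg$source` is set, all couples
#' originate from that fixed point (point-source mode).
#'
#' @param n Number of couples (>= 1).
#' @param cfg A [pg_config()].
#' @return `data.frame` with `event_id`, `x`, `y`, `z` (cm, spectrometer
#'   frame) and `t_emit` (ns, 0 by construction).
#' @export
sample_couples <- function(n, cfg = pg_config()) {
  stopifnot(n >= 1)
  if (!is.null(cfg$source)) {
    pts <- matrix(rep(as.numeric(cfg$source), each = n), ncol = 3)
  } else {
    bp <- as_beam_params(cfg)
    prof <- pg_emission_profile(cfg$E0, params = bp, model = as_xs_model(cfg))
    cdf <- cumsum(prof$density)
    cdf <- cdf / cdf[length(cdf)]
    keep <- !duplicated(cdf)
    depth <- stats::approx(cdf[keep], prof$z[keep], xout = runif(n),
                           rule = 2)$y
    z <- depth - range_from_energy(cfg$ref_energy, bp)
    pts <- cbind(rnorm(n, 0, bp$sigma_lateral),
                 rnorm(n, 0, bp$sigma_lateral), z)
  }
  data.frame(event_id = seq_len(n), x = pts[, 1], y = pts[, 2], z = pts[, 3],
             t_emit = 0)
}

## vectorised detector response for a batch of gammas.
## Flight time is measured to the TRUE interaction point; the recorded hit is
## that point plus Gaussian scatter clipped to the crystal volume, so the
## sphere radius is exact but its centre is wrong by ~hit_sigma -- the
## uncertainty the torus tube absorbs.
.detect_gammas <- function(emissions, energies, dirs, spec, cfg) {
  n <- nrow(emissions)
  tr <- .trace_rays(emissions, dirs, spec)
  hit <- !is.na(tr$det) & is.finite(tr$t_entry)
  det <- rep(NA_integer_, n)
  E_rec <- t_rec <- rep(NA_real_, n)
  P_rec <- matrix(NA_real_, n, 3)
  if (!any(hit)) {
    return(data.frame(det = det, E = E_rec, t = t_rec, x = P_rec[, 1],
                      y = P_rec[, 2], z = P_rec[, 3], detected = hit))
  }
  hit[hit] <- runif(sum(hit)) <= cfg$p_fe
  idx <- which(hit)
  m <- length(idx)
  if (m == 0) {
    return(data.frame(det = det, E = E_rec, t = t_rec, x = P_rec[, 1],
                      y = P_rec[, 2], z = P_rec[, 3], detected = hit))
  }
  chord <- tr$t_exit[idx] - tr$t_entry[idx]
  lam <- cfg$attenuation_length
  u <- runif(m)
  dint <- -lam * log(1 - u * (1 - exp(-chord / lam)))
  dint <- pmin(dint, chord)
  P_true <- emissions[idx, , drop = FALSE] +
    (tr$t_entry[idx] + dint) * dirs[idx, , drop = FALSE]
  tof <- sqrt(rowSums((P_true - emissions[idx, , drop = FALSE])^2)) / C_LIGHT
  if (cfg$timing_sigma > 0) tof <- tof + rnorm(m, 0, cfg$timing_sigma)

  P <- P_true
  if (cfg$hit_sigma > 0) {
    centres <- spec$centres[tr$det[idx], , drop = FALSE]
    axes <- spec$axes[tr$det[idx], , drop = FALSE]
    P <- P_true + matrix(rnorm(3 * m, 0, cfg$hit_sigma), m, 3)
    for (try in 1:20) {
      q <- P - centres
      a <- rowSums(q * axes)
      r2 <- rowSums(q * q) - a^2
      bad <- a < 0 | a > spec$crystal_length | r2 > spec$crystal_radius^2
      if (!any(bad)) break
      P[bad, ] <- P_true[bad, , drop = FALSE] +
        matrix(rnorm(3 * sum(bad), 0, cfg$hit_sigma), sum(bad), 3)
    }
    # clamp any stragglers onto the crystal
    q <- P - centres
    a <- rowSums(q * axes)
    r2 <- pmax(rowSums(q * q) - a^2, 0)
    a_cl <- pmin(pmax(a, 1e-6), spec$crystal_length - 1e-6)
    scale <- ifelse(r2 > spec$crystal_radius^2,
                    (spec$crystal_radius - 1e-6) / sqrt(r2), 1)
    radial <- q - a * axes
    P <- centres + a_cl * axes + radial * scale
  }

  sig_E <- cfg$energy_res_fwhm * energies[idx] / (2 * sqrt(2 * log(2)))
  E_sm <- energies[idx] + rnorm(m, 0, sig_E)

  det[idx] <- tr$det[idx] - 1L   # detector ids are 0-based
  E_rec[idx] <- E_sm
  t_rec[idx] <- tof
  P_rec[idx, ] <- P
  data.frame(det = det, E = E_rec, t = t_rec, x = P_rec[, 1], y = P_rec[, 2],
             z = P_rec[, 3], detected = hit)
}

#' Detector response for a single gamma
#'
#' Traces the gamma to the first crystal entered; with probability `p_fe` a
#' full-energy event is recorded: the interaction depth is sampled along the
#' internal chord from a truncated exponential, the recorded position adds
#' Gaussian scatter clipped to the crystal, the energy is smeared with the
#' fractional-FWHM resolution, and the time is the true flight time plus
#' optional jitter.
#'
#' @param emission Emission point, cm.
#' @param energy Gamma energy, MeV.
#' @param direction Unit emission direction.
#' @param spec A [build_spectrometer()] object.
#' @param cfg A [pg_config()].
#' @return `NULL` when no crystal is hit or the full-energy Bernoulli fails;
#'   otherwise a one-row `data.frame` with `det` (0-based), `E` (MeV), `t`
#'   (ns, emission to arrival), `x`, `y`, `z` (cm).
#' @export
detect_gamma <- function(emission, energy, direction, spec, cfg = pg_config()) {
  if (abs(.norm3(direction) - 1) > 1e-9)
    stop("direction must be a unit vector")
  res <- .detect_gammas(matrix(emission, 1), energy, matrix(direction, 1),
                        spec, cfg)
  if (!res$detected[1]) return(NULL)
  res[1, c("det", "E", "t", "x", "y", "z")]
}

#' Generate a synthetic detected-event table
#'
#' For each sampled couple both gammas (2.741 and 6.128 MeV) are emitted
#' isotropically and independently; detected events share the couple's
#' `event_id` (the bunch index). Optional background singles (uniform energy
#' 0.1-7 MeV, uniform crystal, position and arrival time) are interleaved into
#' random bunches. The table is sorted by time then event_id.
#'
#' @param cfg A [pg_config()]; `cfg$seed` seeds the generator.
#' @return Object of class `pg_simulation`: list with `events` (columns
#'   `event_id, det, E_MeV, t_ns, x_cm, y_cm, z_cm`), `truth` (one row per
#'   generated couple: `event_id, x_cm, y_cm, z_cm, E0_MeV, n_detected`) and
#'   `summary` (counts).
#' @export
generate_event_table <- function(cfg = pg_config()) {
  stopifnot(inherits(cfg, "pg_config"))
  n <- as.integer(cfg$n_couples)
  if (n < 1) stop("generator stage: n_couples must be >= 1")
  set.seed(as.integer(cfg$seed))
  spec <- as_spectrometer(cfg)
  couples <- sample_couples(n, cfg)

  ems <- as.matrix(couples[, c("x", "y", "z")])
  emissions <- rbind(ems, ems)
  energies <- rep(c(2.741, 6.128), each = n)
  ids <- rep(couples$event_id, 2)
  dirs <- .isotropic_directions(2 * n)

  res <- .detect_gammas(emissions, energies, dirs, spec, cfg)
  got <- res$detected
  events <- data.frame(event_id = ids[got], det = res$det[got],
                       E_MeV = res$E[got], t_ns = res$t[got],
                       x_cm = res$x[got], y_cm = res$y[got],
                       z_cm = res$z[got])

  if (cfg$background_rate > 0) {
    n_bg <- rpois(1, cfg$background_rate * n)
    if (n_bg > 0) {
      bdet <- sample.int(16, n_bg, replace = TRUE)
      ax_d <- runif(n_bg, 0, spec$crystal_length)
      rad <- spec$crystal_radius * sqrt(runif(n_bg))
      phi <- runif(n_bg, 0, 2 * pi)
      bg_pos <- matrix(NA_real_, n_bg, 3)
      for (k in seq_len(n_bg)) {
        fr <- .frame_from_axis(spec$axes[bdet[k], ])
        bg_pos[k, ] <- spec$centres[bdet[k], ] + ax_d[k] * spec$axes[bdet[k], ] +
          rad[k] * (cos(phi[k]) * fr$e1 + sin(phi[k]) * fr$e2)
      }
      bg <- data.frame(event_id = sample.int(n, n_bg, replace = TRUE),
                       det = bdet - 1L, E_MeV = runif(n_bg, 0.1, 7),
                       t_ns = runif(n_bg, 0, 4), x_cm = bg_pos[, 1],
                       y_cm = bg_pos[, 2], z_cm = bg_pos[, 3])
      events <- rbind(events, bg)
    }
  }

  events <- events[order(events$t_ns, events$event_id), , drop = FALSE]
  rownames(events) <- NULL

  n_det <- tabulate(ids[got], nbins = n)
  truth <- data.frame(event_id = couples$event_id, x_cm = couples$x,
                      y_cm = couples$y, z_cm = couples$z, E0_MeV = cfg$E0,
                      n_detected = n_det)
  structure(list(events = events, truth = truth,
                 summary = list(n_couples = n, n_emitted = 2L * n,
                                n_detected = sum(got),
                                n_complete = sum(n_det == 2L),
                                config_hash = config_hash(cfg))),
            class = "pg_simulation")
}

#' @export
print.pg_simulation <- function(x, ...) {
  s <- x$summary
  cat(sprintf("synthetic run: %d couples emitted (%d gammas), %d detected, %d complete couples\n",
              s$n_couples, s$n_emitted, s$n_detected, s$n_complete))
  invisible(x)
}
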