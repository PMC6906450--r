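# Couple selection, torus construction from couples, virtual-position
# reconstruction bookkeeping and the position histogram.

mk_events <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(event_id = r[1], det = r[2], E_MeV = r[3], t_ns = r[4],
               x_cm = r[5], y_cm = r[6], z_cm = r[7])))
  df
}

test_that("couple selection applies windows, detectors and multiplicity rules", {
  cfg <- pg_config()
  win <- energy_windows()
  # the canonical accepted couple
  ev <- mk_events(c(1, 3, 2.70, 0.40, 8, 0, 0), c(1, 9, 6.10, 0.41, -8, 0, 0))
  expect_equal(nrow(select_couples(ev, win, cfg)), 1L)
  # same detector rejected
  ev2 <- mk_events(c(1, 3, 2.70, 0.40, 8, 0, 0), c(1, 3, 6.10, 0.41, 8, 0, 0))
  expect_equal(nrow(select_couples(ev2, win, cfg)), 0L)
  # both energies in the same window rejected
  ev3 <- mk_events(c(1, 3, 2.70, 0.40, 8, 0, 0), c(1, 9, 2.70, 0.41, -8, 0, 0))
  expect_equal(nrow(select_couples(ev3, win, cfg)), 0L)
  # boundary energies are inclusive
  ev4 <- mk_events(c(1, 3, 2.659, 0.40, 8, 0, 0), c(1, 9, 6.321, 0.41, -8, 0, 0))
  expect_equal(nrow(select_couples(ev4, win, cfg)), 1L)
  # three events in the window reject the whole window
  ev5 <- mk_events(c(1, 3, 2.70, 0.40, 8, 0, 0), c(1, 9, 6.10, 0.41, -8, 0, 0),
                   c(1, 5, 1.00, 0.42, 0, 8, 0))
  sel5 <- select_couples(ev5, win, cfg)
  expect_equal(nrow(sel5), 0L)
  expect_equal(attr(sel5, "counts")$n_rejected_multi, 1L)
  # events in different bunches are never paired
  ev6 <- mk_events(c(1, 3, 2.70, 0.40, 8, 0, 0), c(2, 9, 6.10, 0.41, -8, 0, 0))
  expect_equal(nrow(select_couples(ev6, win, cfg)), 0L)
  # events far apart in time within a bunch are not coincident
  ev7 <- mk_events(c(1, 3, 2.70, 0.40, 8, 0, 0), c(1, 9, 6.10, 9.00, -8, 0, 0))
  expect_equal(nrow(select_couples(ev7, win, cfg)), 0L)
  # empty input
  expect_equal(nrow(select_couples(ev[0, ], win, cfg)), 0L)
})

test_that("escape-peak windows extend acceptance only when enabled", {
  cfg <- pg_config()
  ev <- mk_events(c(1, 3, 2.230, 0.40, 8, 0, 0),   # single escape of 2.741
                  c(1, 9, 6.10, 0.41, -8, 0, 0))
  expect_equal(nrow(select_couples(ev, energy_windows(FALSE), cfg)), 0L)
  expect_equal(nrow(select_couples(ev, energy_windows(TRUE), cfg)), 1L)
  we <- energy_windows(TRUE)
  expect_equal(nrow(we), 6L)
  expect_true(all(we$lo < we$hi))
})

test_that("selected couples always satisfy the selection contract", {
  cfg <- pg_config()
  win <- energy_windows()
  set.seed(17)
  n_found <- 0L
  for (rep in 1:20) {
    n <- 60
    # energies concentrated around the two lines so that couples do occur
    E <- c(runif(n / 3, 2.6, 2.9), runif(n / 3, 5.9, 6.4),
           runif(n / 3, 0.5, 7))
    ev <- data.frame(event_id = sample(1:12, n, replace = TRUE),
                     det = sample(0:15, n, replace = TRUE),
                     E_MeV = sample(E),
                     t_ns = runif(n, 0, 3),
                     x_cm = rnorm(n, sd = 5), y_cm = rnorm(n, sd = 5),
                     z_cm = rnorm(n, sd = 5))
    sel <- select_couples(ev, win, cfg)
    if (nrow(sel) == 0) next
    n_found <- n_found + nrow(sel)
    expect_true(all(sel$det1 != sel$det2))
    expect_true(all(abs(sel$t1 - sel$t2) <= cfg$coincidence_window))
    g1 <- pgrange:::.classify_energy(sel$E1, win)
    g2 <- pgrange:::.classify_energy(sel$E2, win)
    expect_true(all(!is.na(g1) & !is.na(g2) & g1 != g2))
  }
  expect_gt(n_found, 0)  # the generated tables do exercise the selector
})

test_that("selection count equals the truth-level complete in-window couples", {
  cfg <- pg_config(n_couples = 20000L, seed = 9L)
  sim <- generate_event_table(cfg)
  win <- energy_windows()
  sel <- select_couples(sim$events, win, cfg)
  # independent recount from the truth sidecar: bunches with exactly two
  # detected gammas, different detectors, one energy in each window
  byid <- split(sim$events, sim$events$event_id)
  manual <- sum(vapply(byid, function(b) {
    if (nrow(b) != 2) return(FALSE)
    g <- pgrange:::.classify_energy(b$E_MeV, win)
    b$det[1] != b$det[2] && !any(is.na(g)) && g[1] != g[2] &&
      abs(diff(b$t_ns)) <= cfg$coincidence_window
  }, logical(1)))
  expect_equal(nrow(sel), manual)
})

test_that("a noise-free couple maps to a torus holding the emission point", {
  set.seed(4)
  cfg <- pg_config()
  for (k in 1:25) {
    p0 <- rnorm(3, sd = 0.5)
    cp <- make_noise_free_couple(p0)
    couple <- data.frame(det1 = 0L, E1 = 2.741,
                         t1 = cp$s1$radius / pg_constants()$c_cm_per_ns,
                         x1 = cp$s1$center[1], y1 = cp$s1$center[2],
                         z1 = cp$s1$center[3],
                         det2 = 1L, E2 = 6.128,
                         t2 = cp$s2$radius / pg_constants()$c_cm_per_ns,
                         x2 = cp$s2$center[1], y2 = cp$s2$center[2],
                         z2 = cp$s2$center[3], event_id = k)
    tor <- couple_to_torus(couple, cfg)
    expect_false(is.null(tor))
    # emission point on the spine: surface distance equals the tube radius
    expect_lt(abs(point_torus_distance(p0, tor) - tor$minor_radius), 1e-6)
    expect_lte(point_torus_distance(p0, tor), tor$minor_radius + 1e-6)
  }
  # far-apart hits with short radii: disjoint spheres drop the couple
  bad <- data.frame(det1 = 0L, E1 = 2.741, t1 = 5 / pg_constants()$c_cm_per_ns,
                    x1 = -15, y1 = 0, z1 = 0, det2 = 1L, E2 = 6.128,
                    t2 = 5 / pg_constants()$c_cm_per_ns, x2 = 15, y2 = 0,
                    z2 = 0, event_id = 1L)
  expect_null(couple_to_torus(bad, cfg))
})

test_that("reconstruction bookkeeping counts pairs, nulls and positions", {
  cfg <- pg_config(R_spec = 8, n_u = 60L, n_v = 12L)
  # three small tori inside the region but mutually disjoint
  tori <- list(pg_torus(c(-5, 0, 0), c(0, 0, 1), 1, 0.2),
               pg_torus(c(5, 0, 0), c(0, 0, 1), 1, 0.2),
               pg_torus(c(0, 5, 0), c(1, 0, 0), 1, 0.2))
  vps <- reconstruct_virtual_positions(tori, cfg)
  expect_equal(vps$n, 3L)
  expect_equal(vps$n_pairs, 3L)
  expect_equal(vps$n_nan, 3L)
  expect_equal(vps$n_positions, 0L)
  expect_equal(vps$eq_nominal_positions, 2L * 3L - 3L)
  # fewer than two tori: empty set with n recorded
  one <- reconstruct_virtual_positions(tori[1], cfg)
  expect_equal(one$n, 1L)
  expect_equal(one$n_positions, 0L)
})

test_that("position histogram conserves counts and translates cleanly", {
  cfg <- pg_config()
  set.seed(6)
  P <- cbind(runif(500, -1.5, 1.5), runif(500, -1.5, 1.5),
             runif(500, -3, 3))
  h <- histogram_positions(P, voxel = 0.1, cfg = cfg)
  expect_equal(sum(h$counts), 500)
  expect_equal(h$n_dropped, 0)

  single <- histogram_positions(matrix(c(0.51, -0.22, 1.03), 1), voxel = 0.1,
                                cfg = cfg)
  expect_equal(sum(single$counts), 1)
  expect_equal(max(single$counts), 1)

  # shifting all positions by one voxel shifts the z-marginal argmax by one
  peak <- matrix(rep(c(0.05, 0.05, 1.05), each = 50), ncol = 3)
  shifted <- peak
  shifted[, 3] <- shifted[, 3] - 0.1
  h1 <- histogram_positions(peak, voxel = 0.1, cfg = cfg)
  h2 <- histogram_positions(shifted, voxel = 0.1, cfg = cfg)
  m1 <- hist_marginal(h1, "z"); m2 <- hist_marginal(h2, "z")
  expect_equal(which.max(m1$count) - which.max(m2$count), 1L)

  # positions outside the phantom bounds are dropped and counted
  out <- histogram_positions(matrix(c(5, 0, 0), 1), voxel = 0.1, cfg = cfg)
  expect_equal(out$n_dropped, 1)
})

test_that("noise-free point source is recovered at the true depth", {
  src <- c(0.2, -0.3, 0.5)
  cfg <- point_source_config(src, 1200, seed = 12L)
  sim <- generate_event_table(cfg)
  sel <- select_couples(sim$events, energy_windows(), cfg)
  expect_gt(nrow(sel), 20)
  tori <- couples_to_tori(sel, cfg)
  vps <- reconstruct_virtual_positions(tori, cfg)
  h <- histogram_positions(vps, voxel = cfg$voxel, cfg = cfg)
  mz <- hist_marginal(h, "z")
  expect_lt(abs(mz$center[which.max(mz$count)] - src[3]), cfg$voxel + 1e-9)
  mx <- hist_marginal(h, "x")
  expect_lt(abs(mx$center[which.max(mx$count)] - src[1]), cfg$voxel + 1e-9)
})

test_that("reconstructed depth spread grows with the hit-position scatter", {
  # seed-averaged fitted width at 0, 3 and 6 mm scatter must be increasing
  sig <- sapply(c(101L, 202L, 303L), function(seed) {
    vapply(c(0, 0.3, 0.6), function(hs) {
      cfg <- pg_config(n_couples = 30000L, seed = seed, hit_sigma = hs)
      run_pipeline(cfg)$sigma_mm
    }, numeric(1))
  })
  expect_true(all(diff(rowMeans(sig)) > 0))
})
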