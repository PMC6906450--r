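# Event generator: sampling, detector response, determinism and truth
# consistency.

test_that("couple sampling reproduces the beam's lateral and depth structure", {
  cfg <- pg_config(seed = 1L)
  set.seed(1)
  cp <- sample_couples(1e4, cfg)
  expect_equal(sd(cp$x), 0.4, tolerance = 0.05)
  expect_equal(sd(cp$y), 0.4, tolerance = 0.05)
  expect_true(all(cp$t_emit == 0))

  # depth histogram argmax within 2 mm of the analytic profile argmax
  set.seed(2)
  cp <- sample_couples(3e5, cfg)
  bp <- pgrange:::as_beam_params(cfg)
  depth <- cp$z + range_from_energy(cfg$ref_energy, bp)
  h <- hist(depth, breaks = seq(0, 30, by = 0.1), plot = FALSE)
  argmax <- h$mids[which.max(h$counts)]
  expect_lt(abs(argmax - expected_pg_depth(180, bp)), 0.2)

  # point-source mode pins every couple to the source
  cps <- sample_couples(50, pg_config(source = c(0.1, -0.2, 0.3)))
  expect_true(all(cps$x == 0.1 & cps$y == -0.2 & cps$z == 0.3))
})

test_that("generation is deterministic given the seed", {
  cfg <- pg_config(n_couples = 3000L, seed = 99L)
  a <- generate_event_table(cfg)
  b <- generate_event_table(cfg)
  expect_identical(a$events, b$events)
  expect_identical(a$truth, b$truth)
})

test_that("recorded energies carry the 3% FWHM resolution", {
  cfg <- point_source_config(c(0, 0, 0), 30000, seed = 5L,
                             energy_res_fwhm = 0.03)
  sim <- generate_event_table(cfg)
  E_hi <- sim$events$E_MeV[sim$events$E_MeV > 4]
  expect_gt(length(E_hi), 2000)
  fwhm <- sd(E_hi) * 2 * sqrt(2 * log(2))
  expect_equal(fwhm, 0.03 * 6.128, tolerance = 0.05)
})

test_that("every recorded hit lies inside its crystal", {
  cfg <- pg_config(n_couples = 20000L, seed = 3L)
  sim <- generate_event_table(cfg)
  sp <- pgrange:::as_spectrometer(cfg)
  P <- as.matrix(sim$events[, c("x_cm", "y_cm", "z_cm")])
  ok <- logical(nrow(P))
  for (k in 1:16) {
    rows <- sim$events$det == k - 1L
    if (!any(rows)) next
    ok[rows] <- pgrange:::.in_crystal(P[rows, , drop = FALSE],
                                      sp$centres[k, ], sp$axes[k, ],
                                      sp$crystal_length, sp$crystal_radius,
                                      tol = 1e-6)
  }
  expect_true(all(ok))
})

test_that("with all noise off the sphere radius equals the emission-to-hit distance", {
  src <- c(0.2, -0.1, 0.4)
  cfg <- point_source_config(src, 4000, seed = 8L)
  sim <- generate_event_table(cfg)
  d <- sqrt(rowSums(sweep(as.matrix(sim$events[, c("x_cm", "y_cm", "z_cm")]),
                          2, src)^2))
  r <- sim$events$t_ns * pg_constants()$c_cm_per_ns
  expect_lt(max(abs(r - d)), 1e-9)
})

test_that("complete-couple fraction matches the squared solid-angle coverage", {
  cfg <- point_source_config(c(0, 0, 0), 20000, seed = 21L)
  sim <- generate_event_table(cfg)
  frac <- sim$summary$n_complete / sim$summary$n_couples
  sa <- solid_angle_fraction(pgrange:::as_spectrometer(cfg),
                             n_samples = 2e5, seed = 22)
  se_frac <- sqrt(frac * (1 - frac) / sim$summary$n_couples)
  se_sa2 <- 2 * sa$fraction * sa$se
  expect_lt(abs(frac - sa$fraction^2), 3 * sqrt(se_frac^2 + se_sa2^2))
})

test_that("complete-couple yield decreases with spectrometer radius", {
  yields <- vapply(c(8, 15, 25), function(R) {
    cfg <- point_source_config(c(0, 0, 0), 20000, seed = 31L, R_spec = R)
    generate_event_table(cfg)$summary$n_complete
  }, numeric(1))
  expect_true(all(diff(yields) < 0))
})

test_that("truth sidecar and event table are consistent", {
  cfg <- pg_config(n_couples = 5000L, seed = 13L, background_rate = 0.1)
  sim <- generate_event_table(cfg)
  expect_true(all(sim$events$event_id %in% sim$truth$event_id))
  expect_equal(nrow(sim$truth), 5000L)
  expect_equal(sum(sim$truth$n_detected), sim$summary$n_detected)
  expect_true(all(sim$truth$n_detected %in% 0:2))
})
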