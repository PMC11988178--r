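test_that("zero-width beams are filiform and sampling is seed-deterministic", {
  b <- beam_spec(mean_energy = 6.0, fwhm_energy = 0, fwhm_alpha = 0, spot = 0)
  s <- sample_primaries(b, 50)
  expect_true(all(s$energy_mev == 6.0))
  expect_true(all(s$u == 0 & s$v == 0 & s$w == 1))
  expect_true(all(s$x == 0 & s$y == 0))
  b2 <- beam_spec(fwhm_energy = 0.3, fwhm_alpha = 0.5, spot = 0.2, seed = 77)
  expect_identical(sample_primaries(b2, 1000), sample_primaries(b2, 1000))
})

test_that("sampled energy moments match the Gaussian specification", {
  b <- beam_spec(mean_energy = 6.0, fwhm_energy = 0.1, fwhm_alpha = 0, spot = 0)
  s <- sample_primaries(b, 1e5, seed = 31)
  expect_lt(abs(mean(s$energy_mev) - 6.0), 0.002)
  fwhm_hat <- sd(s$energy_mev) * 2 * sqrt(2 * log(2))
  expect_lt(abs(fwhm_hat - 0.1), 0.005)
})

test_that("tracking in a null field is a straight line", {
  fm <- uniform_field_map(0)
  tr <- track(electron_state(), fm, step = 0.5, max_length = 4.2)
  endpoint <- c(tail(tr$x, 1), tail(tr$y, 1), tail(tr$z, 1))
  expect_equal(endpoint, c(0, 0, 4.2), tolerance = 1e-12)
})

test_that("a 6 MeV electron in 1 T gyrates at the analytic radius", {
  fm <- uniform_field_map(1)
  tr <- track(electron_state(), fm, step = 0.02, max_length = 14)
  pc <- sqrt(6 * (6 + 2 * 0.51099895))
  r_expected <- pc / 2.99792458 # 2.165 cm
  r_measured <- (max(tr$x) - min(tr$x)) / 2
  expect_lt(abs(r_measured - r_expected) / r_expected, 1e-3)
  expect_lt(abs(r_expected - 2.165), 5e-4)
  # magnetic force does no work
  expect_true(all(abs(tr$energy_mev - 6) < 6e-9))
  expect_true(all(abs(tr$u^2 + tr$v^2 + tr$w^2 - 1) < 1e-9))
})

test_that("halving the step reduces the endpoint error at second order", {
  fm <- uniform_field_map(1)
  pc <- sqrt(6 * (6 + 2 * 0.51099895))
  r <- pc / 2.99792458
  quarter <- pi * r / 2
  err <- vapply(c(0.2, 0.1, 0.05), function(ds) {
    tr <- track(electron_state(), fm, step = ds, max_length = quarter)
    endpoint <- c(tail(tr$x, 1), tail(tr$z, 1))
    th <- quarter / r
    exact <- c(sign(endpoint[1]) * r * (1 - cos(th)), r * sin(th))
    sqrt(sum((endpoint - exact)^2))
  }, numeric(1))
  expect_gte(err[1] / err[2], 4)
  expect_gte(err[2] / err[3], 4)
})

test_that("oversized steps trigger the accuracy warning", {
  fm <- uniform_field_map(1, spacing = 0.5)
  expect_warning(track(electron_state(), fm, step = 1, max_length = 2),
    "spacing")
})

test_that("synthetic dipole maps have an exact plateau, symmetry and fringe", {
  fm <- generate_dipole_map(1, pole_gap = 3, extent = 6, edge_softness = 1,
    spacing = 0.2)
  ctr <- (fm$dim + 1) / 2
  expect_identical(fm$B[ctr[1], ctr[2], ctr[3], 2], 1)
  by <- fm$B[, , , 2]
  expect_equal(by, by[rev(seq_len(fm$dim[1])), , ], tolerance = 1e-12)
  expect_equal(by, by[, rev(seq_len(fm$dim[2])), ], tolerance = 1e-12)
  expect_equal(by, by[, , rev(seq_len(fm$dim[3]))], tolerance = 1e-12)
  edge <- max(by[1, , ], by[fm$dim[1], , ], by[, , 1], by[, , fm$dim[3]])
  expect_gte(1 / edge, 10)
})

test_that("canal transmission: aligned beam passes, displaced beam is lost", {
  fm <- uniform_field_map(0, half = 6)
  aligned <- lapply(1:20, function(i) {
    track(electron_state(z = -1), fm, step = 0.1, max_length = 8)
  })
  expect_identical(transmission_fraction(aligned, 10, 50), 1.0)
  displaced <- lapply(1:10, function(i) {
    track(electron_state(x = 2, z = -1), fm, step = 0.1, max_length = 8)
  })
  expect_identical(transmission_fraction(displaced, 10, 50), 0.0)
  expect_error(transmission_fraction(list(), 10, 50), "trajectories")
})

test_that("a tuned dipole guides a realistic beam through the canal", {
  tuned <- tune_dipole(18.43, energy_mev = 6, start = c(0, 0, -6),
    bounds = c(0.01, 0.5), pole_gap = 3, extent = 8, edge_softness = 1,
    spacing = 0.2)
  expect_lt(abs(tuned$strength), 3)
  ref <- tuned$reference
  exit_dir <- c(tail(ref$u, 1), tail(ref$v, 1), tail(ref$w, 1))
  expect_lt(abs(atan2(abs(exit_dir[1]), exit_dir[3]) * 180 / pi - 18.43), 0.05)
  # place the canal on the reference path just downstream of the magnet
  i_c <- which.min(abs(ref$s - 15))
  canal_origin <- c(ref$x[i_c], ref$y[i_c], ref$z[i_c])
  beam <- beam_spec(fwhm_energy = 0.1, fwhm_alpha = 0.1, spot = 0.05)
  prim <- sample_primaries(beam, 60, origin = c(0, 0, -6), seed = 5)
  trajs <- lapply(seq_len(nrow(prim)), function(i) {
    track(prim[i, ], tuned$field, step = 0.05, max_length = 30,
      outside = "free")
  })
  frac <- transmission_fraction(trajs, 10, 50,
    canal_origin = canal_origin, canal_axis = exit_dir)
  expect_gte(frac, 0.9)
})
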