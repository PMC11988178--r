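test_that("voxel traversal reproduces analytic chord lengths", {
  ph <- make_water_cube(side = 4, spacing = 0.2)
  # axis-aligned ray through voxel centres
  p <- voxel_path(ph, origin = c(-5, 0.01, 0.01), direction = c(1, 0, 0))
  expect_identical(nrow(p), 20L)
  expect_true(all(abs(p$length - 0.2) < 1e-10))
  expect_lt(abs(sum(p$length) - 4), 1e-10)
  # 45-degree ray: oracle from sorted plane-crossing parameters
  org <- c(-3, -3 + 0.07, 0.01)
  dir <- c(1, 1, 0) / sqrt(2)
  p45 <- voxel_path(ph, org, dir)
  bounds <- seq(-2, 2, by = 0.2)
  tx <- (bounds - org[1]) / dir[1]
  ty <- (bounds - org[2]) / dir[2]
  tt <- sort(c(tx, ty))
  tt <- tt[tt >= max(min(tx), min(ty)) - 1e-12 &
    tt <= min(max(tx), max(ty)) + 1e-12]
  oracle <- diff(tt)
  oracle <- oracle[oracle > 1e-12]
  expect_equal(sum(p45$length), sum(oracle), tolerance = 1e-10)
  expect_equal(p45$length, oracle, tolerance = 1e-10)
})

test_that("a void phantom receives no dose", {
  ph <- voxel_phantom(array("air", dim = c(10, 10, 10)), spacing = 0.5,
    densities = c(air = 0))
  rec <- random_phase_space(200, seed = 2)
  rec$kpar <- rep(2L, 200)
  d <- deposit(rec, ph)
  expect_true(all(d$dose == 0))
  expect_identical(sum(d$edep_mev), 0)
  # nothing interacts: everything that entered escapes
  expect_equal(d$tallies[["escaped"]], d$tallies[["entered"]],
    tolerance = 1e-12)
})

test_that("slab-to-slab attenuation follows the closed form", {
  ph <- make_water_cube(side = 8, spacing = 0.2)
  rec <- cxbeam:::new_phase_space(
    tibble::tibble(kpar = 2L, energy_mev = 1.25, x = 0.01, y = 0.01,
      z = -10, u = 0, v = 0, w = 1),
    n_primaries = 1)
  d <- deposit(rec, ph, n_batches = 1L)
  iz <- cut(voxel_centers(d)$z, seq(-4, 4, by = 2), labels = FALSE)
  slab <- vapply(1:4, function(k) sum(d$edep_mev[, , which(iz == k)]),
    numeric(1))
  mu <- mu_over_rho("water", 1.25)
  ratio_expected <- exp(-mu * 2)
  for (k in 1:3) {
    expect_lt(abs(slab[k + 1] / slab[k] - ratio_expected), 1e-4)
  }
})

test_that("energy bookkeeping balances to numerical precision", {
  rec <- small_emission(2e4, diameter_mm = 10, seed = 77)
  ph <- make_water_cube(side = 10, spacing = 0.2)
  d <- deposit(rec, ph)
  entered <- d$tallies[["entered"]]
  balance <- sum(d$edep_mev) + d$tallies[["scatter"]] + d$tallies[["escaped"]]
  expect_lt(abs(entered - balance) / entered, 1e-9)
  expect_lte(sum(d$edep_mev), entered)
})

test_that("focal-sphere dose averages behave on synthetic fields", {
  u <- make_dose_grid(array(2.5, dim = c(21, 21, 21)), spacing = 0.2)
  expect_identical(dose_in_focal_sphere(u), 2.5)
  z <- make_dose_grid(array(0, dim = c(21, 21, 21)), spacing = 0.2)
  expect_identical(dose_in_focal_sphere(z), 0)
  # indicator of the sphere itself comes back as 1 despite voxelization
  g <- make_dose_grid(array(0, dim = c(41, 41, 41)), spacing = 0.1)
  cc <- voxel_centers(g)
  r2 <- outer(outer(cc$x^2, cc$y^2, "+"), cc$z^2, "+")
  g$dose[r2 <= 1] <- 1
  expect_equal(dose_in_focal_sphere(g, radius = 1), 1)
  expect_error(dose_in_focal_sphere(u, center = c(100, 0, 0)), "sphere")
})

test_that("the focal dose is stable when the history count doubles", {
  ph <- make_water_cube(side = 10, spacing = 0.4)
  d_at <- function(n, seed) {
    rec <- small_emission(n, diameter_mm = 10, seed = seed)
    turned <- integrate_turn(rec, 12)
    dose_in_focal_sphere(deposit(turned, ph))
  }
  reps <- vapply(1:5, function(i) d_at(2e4, 100 + i), numeric(1))
  se_single <- sd(reps)
  D1 <- mean(reps)
  D2 <- d_at(4e4, 202)
  # combined spread of a 2e4-run mean (5 reps) and one 4e4 run
  expect_lt(abs(D1 - D2), 3 * se_single * sqrt(1 / 5 + 1 / 2))
})

test_that("a convergence study against itself reports zero deviation", {
  cfg <- run_config(
    beam = beam_spec(n_histories = 2000),
    collimator = collimator_spec(10, 100), turn_steps = 8L,
    phantom = list(type = "water_cube", side = 8, spacing = 0.4),
    seed = 3
  )
  st <- convergence_study(cfg, n_list = 2000, reference_n = 2000, seed = 7)
  expect_identical(st$delta_pct, 0)
  expect_error(convergence_study(cfg, n_list = 4000, reference_n = 2000),
    "reference")
})
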