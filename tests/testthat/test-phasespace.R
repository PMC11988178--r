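test_that("bremsstrahlung spectrum is normalised, bounded and matches its analytic mean", {
  tg <- target_spec()
  sp <- brems_spectrum(6, tg)
  expect_lt(abs(sum(sp$weight) - 1), 1e-12)
  e <- sample_spectrum(sp, 2e5, seed = 4)
  expect_lte(max(e), 6)
  expect_gte(min(e), 0.05)
  # independent quadrature of the Kramers + self-filtration form
  eg <- seq(0.05, 6, length.out = 20001)
  dens <- (6 - eg) / eg *
    exp(-mu_over_rho("tungsten", eg) * 19.3 * 0.115 / 2)
  m_oracle <- sum(eg * dens) / sum(dens)
  se <- sd(e) / sqrt(length(e))
  expect_lt(abs(mean(e) - m_oracle), 3 * se)
  expect_error(brems_spectrum(0.01), "cutoff|span")
})

test_that("emission honours the collimator acceptance", {
  rec <- small_emission(2e4, diameter_mm = 10, seed = 55)
  expect_gt(nrow(rec), 0)
  expect_true(all(abs(rec$u^2 + rec$v^2 + rec$w^2 - 1) < 1e-6))
  expect_true(all(rec$z == -21))
  # every record lies within the bore radius of the beam axis at the
  # scoring plane (still inside the bore there)
  fr <- cxbeam:::device_frame(convergent_geometry(), 0.2,
    collimator_spec(10, 100))
  rel <- cbind(rec$x - fr$source[1], rec$y - fr$source[2],
    rec$z - fr$source[3])
  ax <- as.vector(rel %*% fr$axis)
  rad <- sqrt(rowSums(rel^2) - ax^2)
  expect_true(all(rad <= fr$r_bore + 1e-9))
  # vanishing aperture emits nothing
  rec0 <- small_emission(5e3, diameter_mm = 1e-6, seed = 55)
  expect_identical(nrow(rec0), 0L)
})

test_that("emitted count scales with the collimator solid angle", {
  b <- beam_spec(fwhm_energy = 0, fwhm_alpha = 0, spot = 0)
  prim <- sample_primaries(b, 1e6, seed = 2)
  geom <- convergent_geometry()
  fr <- cxbeam:::device_frame(geom, 0.2, collimator_spec(6, 100))
  hits <- cxbeam:::guide_to_target(prim, fr)
  n6 <- nrow(emit_phase_space(hits, target_spec(), collimator_spec(6, 100),
    geom, seed = 3, n_photons_per_electron = 1))
  n3 <- nrow(emit_phase_space(hits, target_spec(), collimator_spec(3, 100),
    geom, seed = 3, n_photons_per_electron = 1))
  expect_lt(abs(n6 / n3 - 4), 0.4)
})

test_that("electron mode passes the primaries through as electron records", {
  b <- beam_spec(fwhm_energy = 0, fwhm_alpha = 0, spot = 0)
  prim <- sample_primaries(b, 100, seed = 9)
  geom <- convergent_geometry()
  coll <- collimator_spec(10, 100)
  fr <- cxbeam:::device_frame(geom, 0.2, coll)
  hits <- cxbeam:::guide_to_target(prim, fr)
  rec <- emit_phase_space(hits, target_spec(present = FALSE), coll, geom,
    seed = 1)
  expect_identical(nrow(rec), 100L)
  expect_true(all(rec$kpar == 1L))
  expect_true(all(rec$energy_mev == 6))
})

test_that("phase-space files round-trip at full precision", {
  rec <- random_phase_space(1000, seed = 8)
  path <- withr::local_tempfile(fileext = ".phsp")
  write_phsp(rec, path)
  back <- read_phsp(path)
  for (col in names(rec)) {
    expect_identical(back[[col]], rec[[col]])
  }
  expect_identical(attr(back, "n_primaries"), 1000)
})

test_that("the declared column order and conventions parse correctly", {
  path <- withr::local_tempfile(fileext = ".phsp")
  writeLines(c(
    "# cxbeam phase-space format 1",
    "2 1.25 0.1 0.0 -21.0 0.0 0.0 1.0"
  ), path)
  rec <- read_phsp(path)
  expect_identical(rec$kpar, 2L) # photon
  expect_identical(rec$energy_mev, 1.25)
  expect_identical(c(rec$x, rec$y, rec$z), c(0.1, 0, -21))
  expect_identical(c(rec$u, rec$v, rec$w), c(0, 0, 1))
})

test_that("malformed files are rejected with a line number", {
  path <- withr::local_tempfile(fileext = ".phsp")
  writeLines(c("# header", "2 1.0 0 0 0 0 0 1", "2 1.0 0 0 0 0 1"), path)
  expect_error(read_phsp(path), "line 3")
  path2 <- withr::local_tempfile(fileext = ".phsp")
  writeLines("2 1.0 0 0 0 0.5 0.5 1.0", path2) # norm 1.5
  expect_error(read_phsp(path2), "norm")
})

test_that("turn integration rotates records as a rigid set", {
  rec <- random_phase_space(50, seed = 3)
  one <- integrate_turn(rec, 1)
  expect_equal(one$x, rec$x)
  expect_equal(one$u, rec$u)
  r1 <- cxbeam:::new_phase_space(
    tibble::tibble(kpar = 2L, energy_mev = 1, x = 1, y = 0, z = -21,
      u = 1, v = 0, w = 0), n_primaries = 1)
  turned <- integrate_turn(r1, 4)
  expect_identical(nrow(turned), 4L)
  expect_equal(turned$x[2], 0, tolerance = 1e-12)
  expect_equal(turned$y[2], 1, tolerance = 1e-12)
  expect_equal(turned$u[2], 0, tolerance = 1e-12)
  expect_equal(turned$v[2], 1, tolerance = 1e-12)
  expect_identical(attr(turned, "n_primaries"), 4)
})

test_that("turn-integrated output is azimuthally symmetric", {
  rec <- small_emission(2e4, diameter_mm = 10, seed = 21)
  turned <- integrate_turn(rec, 360)
  # radial distances are invariant under any further global rotation
  extra <- rotate_phase_space(turned, 37.3, axis = "z")
  br <- seq(0, max(sqrt(turned$x^2 + turned$y^2)) * 1.01, length.out = 30)
  h1 <- hist(sqrt(turned$x^2 + turned$y^2), breaks = br, plot = FALSE)$counts
  h2 <- hist(sqrt(extra$x^2 + extra$y^2), breaks = br, plot = FALSE)$counts
  expect_identical(h1, h2)
  # azimuth is uniform over the turn
  phi <- atan2(turned$y, turned$x)
  counts <- hist(phi, breaks = seq(-pi, pi, length.out = 25),
    plot = FALSE)$counts
  p <- suppressWarnings(chisq.test(counts)$p.value)
  expect_gt(p, 0.01)
})

test_that("diagnostics conserve counts and flag degenerate input", {
  rec <- random_phase_space(500, seed = 12)
  d <- phsp_diagnostics(rec, n_bins = 40)
  expect_identical(sum(d$spectrum$count), 500L)
  for (v in c("x", "y", "z")) {
    expect_identical(sum(d$position$count[d$position$variable == v]), 500L)
  }
  expect_identical(sum(d$particles$count), 500L)
  expect_error(phsp_diagnostics(rec[0, ]), "empty")
  mono <- rec
  mono$energy_mev <- rep(2.5, 500)
  dm <- phsp_diagnostics(mono, n_bins = 40)
  expect_identical(sum(dm$spectrum$count > 0), 1L)
})
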