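geom_fig <- convergent_geometry(L = 30, h = 10)
mono <- beam_spectrum(1.25)

test_that("transversal area follows the (1 - z/F)^2 law", {
  g <- geom_fig
  expect_equal(transversal_area(g, 0), pi * g$r0^2)
  expect_equal(transversal_area(g, g$focal_depth / 2), pi * g$r0^2 / 4)
  g1 <- convergent_geometry(L = 30, h = 10, r0 = 1, focal_depth = 10)
  expect_equal(transversal_area(g1, 9), pi * 0.01)
  expect_error(transversal_area(g, g$focal_depth), "[Dd]egenerate")
  expect_error(transversal_area(g, g$focal_depth * 1.1), "[Dd]egenerate")
})

test_that("surface dose is D0 and the focusing factor is 16 at half focal depth", {
  expect_equal(on_axis_dose(geom_fig, mono, "water", 1, 0, D0 = 2.5), 2.5)
  d_half <- on_axis_dose(geom_fig, mono, "water", 1, geom_fig$focal_depth / 2,
    D0 = 1, attenuation = FALSE)
  expect_identical(d_half, 16)
  # fluence-conservation variant has exponent 1
  d1 <- on_axis_dose(geom_fig, mono, "water", 1, geom_fig$focal_depth / 2,
    D0 = 1, attenuation = FALSE, area_exponent = 1)
  expect_identical(d1, 4)
  expect_error(on_axis_dose(geom_fig, beam_spectrum(1)[0, ], "water", 1, 5),
    "spectrum")
})

test_that("attenuation exponent agrees with a numerical path quadrature", {
  # independent Simpson integration of mu*rho along the oblique ray
  mu <- mu_over_rho("water", 1.25)
  sec_phi <- 1 / cos(geom_fig$phi)
  for (z in c(3, 11.7, 24)) {
    simpson <- integrate(function(s) rep(mu * 1.0, length(s)),
      0, z * sec_phi, rel.tol = 1e-12)$value
    d <- on_axis_dose(geom_fig, mono, "water", 1, z, D0 = 1)
    d_expected <- (1 - z / geom_fig$focal_depth)^-4 * exp(-simpson)
    expect_equal(d, d_expected, tolerance = 1e-6)
  }
})

test_that("the dose law conserves D0 when unwound, and increases with depth", {
  zz <- seq(0, 0.95 * geom_fig$focal_depth, length.out = 120)
  d <- on_axis_dose(geom_fig, mono, "water", 1, zz, D0 = 1)
  a_ratio <- transversal_area(geom_fig, zz) / transversal_area(geom_fig, 0)
  mu <- mu_over_rho("water", 1.25)
  unwound <- d * a_ratio^2 * exp(+mu * zz / cos(geom_fig$phi))
  expect_true(all(abs(unwound - 1) < 1e-10))
  expect_true(all(diff(d) > 0))
})

test_that("poly-energetic attenuation is the weighted bin average", {
  spec <- beam_spectrum(c(0.5, 2), c(0.3, 0.7))
  z <- 10
  d <- on_axis_dose(geom_fig, spec, "water", 1, z, D0 = 1)
  att <- sum(spec$weight *
    exp(-mu_over_rho("water", spec$energy_mev) * z / cos(geom_fig$phi)))
  expect_equal(d, (1 - z / 30)^-4 * att, tolerance = 1e-12)
})

test_that("spread-out profile reduces to the single peak and is linear", {
  g <- convergent_geometry(L = 30, h = 10, focal_spot = 0.15)
  zg <- seq(1, 9.5, length.out = 50)
  single <- psop_profile(g, 10, 1, mono, "water", 1, zg)
  gg <- g
  gg$focal_depth <- 10
  ref <- on_axis_dose(gg, mono, "water", 1, zg)
  expect_equal(single$dose, ref / max(ref), tolerance = 1e-12)
  dbl <- psop_profile(g, c(10, 10), c(0.5, 0.5), mono, "water", 1, zg)
  expect_equal(dbl$dose, single$dose, tolerance = 1e-12)
  expect_error(psop_profile(g, c(8, 10), 1, mono, "water", 1, zg), "length")
})

test_that("plateau flattening is optimal, symmetric and effective", {
  g <- convergent_geometry(L = 30, h = 10, focal_spot = 0.15)
  depths <- seq(8, 12, length.out = 5)
  plateau <- c(8.5, 11.5)
  expect_identical(flatten_weights(g, 10, mono, "water", 1, plateau = c(9, 11)), 1.0)
  w <- flatten_weights(g, depths, mono, "water", 1, plateau)
  # the least-squares problem is order-equivariant
  w_rev <- flatten_weights(g, rev(depths), mono, "water", 1, plateau)
  expect_equal(rev(w_rev), w, tolerance = 1e-6)
  zf <- seq(plateau[1], plateau[2], length.out = 301)
  ripple <- function(wts) {
    p <- psop_profile(g, depths, wts, mono, "water", 1, zf)
    (max(p$dose) - min(p$dose)) / max(p$dose)
  }
  expect_lte(ripple(w), 0.03)
  expect_lte(ripple(w), ripple(rep(1 / 5, 5)) + 1e-12)
  expect_error(flatten_weights(g, depths, mono, "water", 1, c(13, 15)),
    "plateau")
})
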