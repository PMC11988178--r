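test_that("DVH of a uniform structure is a step function", {
  d <- make_dose_grid(array(2, dim = c(5, 5, 5)))
  curve <- dvh(d, dose_axis = c(0, 1, 1.999, 2, 2.5))
  expect_equal(curve$volume_pct, c(100, 100, 100, 100, 0))
})

test_that("DVH enumerates mixed-dose structures exactly and ignores voxel order", {
  arr <- array(0, dim = c(2, 1, 1))
  arr[1, 1, 1] <- 1
  arr[2, 1, 1] <- 3
  d <- make_dose_grid(arr)
  curve <- dvh(d, dose_axis = c(0, 2, 3.5))
  expect_equal(curve$volume_pct, c(100, 50, 0))
  set.seed(2)
  big <- array(runif(4^3), dim = c(4, 4, 4))
  perm <- array(sample(big), dim = dim(big))
  ax <- seq(0, 1, by = 0.05)
  expect_equal(dvh(make_dose_grid(big), dose_axis = ax)$volume_pct,
    dvh(make_dose_grid(perm), dose_axis = ax)$volume_pct)
  expect_error(dvh(make_dose_grid(big), mask = array(FALSE, dim = c(4, 4, 4))),
    "[Ee]mpty")
})

test_that("DVH curves are monotone, start at 100% and end at 0%", {
  g <- gaussian_ball_dose()
  curve <- dvh(g)
  expect_true(all(diff(curve$volume_pct) <= 0))
  expect_identical(curve$volume_pct[1], 100)
  expect_identical(tail(curve$volume_pct, 1), 0)
})

test_that("isodose volumes nest and match the analytic Gaussian level sets", {
  g <- gaussian_ball_dose(n = 41, spacing = 0.1, sigma = 0.5)
  vols <- vapply(c(10, 25, 50, 75, 90), function(l) {
    isodose_volume(g, l)$volume_cm3
  }, numeric(1))
  expect_true(all(diff(vols) < 0))
  for (l in c(25, 50, 75)) {
    r_l <- 0.5 * sqrt(2 * log(100 / l))
    v_exact <- 4 / 3 * pi * r_l^3
    shell <- 4 * pi * r_l^2 * 0.1
    expect_lt(abs(isodose_volume(g, l)$volume_cm3 - v_exact), shell)
  }
  expect_identical(isodose_volume(g, 0)$volume_cm3, sum(g$dose > 0) * 0.1^3)
  expect_gte(isodose_volume(g, 100)$volume_cm3, 0.1^3)
})

test_that("the largest connected component is identified under 6-connectivity", {
  arr <- array(0, dim = c(10, 10, 10))
  arr[2:3, 2:3, 2:3] <- 1 # 8 voxels
  arr[7:9, 7:9, 7:9] <- 1 # 27 voxels
  arr[5, 5, 5] <- 1 # isolated
  d <- make_dose_grid(arr)
  iso <- isodose_volume(d, 50)
  expect_identical(iso$n_components, 3L)
  expect_equal(iso$largest_volume_cm3, 27 * 0.1^3)
})

test_that("mean extension recovers cubes, Gaussian level sets and translations", {
  # uniform dose in a 5 mm cube at 1 mm voxels
  arr <- array(0, dim = c(21, 21, 21))
  arr[9:13, 9:13, 9:13] <- 1
  expect_equal(mean_extension_95(make_dose_grid(arr, spacing = 0.1)), 5,
    tolerance = 0.2)
  # translation invariance
  arr2 <- array(0, dim = c(21, 21, 21))
  arr2[12:16, 12:16, 12:16] <- 1
  expect_identical(mean_extension_95(make_dose_grid(arr2, spacing = 0.1)),
    mean_extension_95(make_dose_grid(arr, spacing = 0.1)))
  # isotropic Gaussian: analytic 95% caliper is 2 sigma sqrt(2 ln(100/95))
  g <- gaussian_ball_dose(n = 41, spacing = 0.1, sigma = 0.5)
  ext_exact <- 2 * 0.5 * sqrt(2 * log(100 / 95)) * 10
  expect_lt(abs(mean_extension_95(g) - ext_exact), 1.0 + 1e-9) # one voxel
  # wider dose ball -> strictly larger extension
  g2 <- gaussian_ball_dose(n = 41, spacing = 0.1, sigma = 0.7)
  expect_gt(mean_extension_95(g2), mean_extension_95(g))
  expect_error(mean_extension_95(make_dose_grid(array(0, dim = c(3, 3, 3)))),
    "zero")
})

test_that("the R50 surface sits at the analytic half-maximum radius", {
  g <- gaussian_ball_dose(n = 41, spacing = 0.1, sigma = 0.5)
  contour <- r50_surface(g)
  cc <- voxel_centers(g)
  idx <- which(contour, arr.ind = TRUE)
  r <- sqrt(cc$x[idx[, 1]]^2 + cc$y[idx[, 2]]^2 + cc$z[idx[, 3]]^2)
  r50_exact <- 0.5 * sqrt(2 * log(2))
  expect_true(all(abs(r - r50_exact) < sqrt(3) * 0.1 + 1e-9))
  # the 50% region is nested inside the 25% region
  m50 <- cxbeam:::isodose_mask(g, 50)
  m25 <- cxbeam:::isodose_mask(g, 25)
  expect_true(all(m25[m50]))
  # uniform dose: the contour is the outer shell of the grid
  u <- make_dose_grid(array(1, dim = c(5, 5, 5)))
  shell <- r50_surface(u)
  expect_identical(sum(shell), 98L)
})
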