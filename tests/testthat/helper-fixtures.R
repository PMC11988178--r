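# synthetic dose grids and small device configurations used across tests

make_dose_grid <- function(dose, spacing = 0.1, density = 1) {
  dm <- dim(dose)
  sp <- rep(spacing, length.out = 3)
  structure(
    list(
      dose = dose, variance = array(0, dm), n_histories = 1,
      origin = -(dm - 1) / 2 * sp, spacing = sp, dim = dm,
      density = array(density, dm),
      tallies = c(entered = 0, escaped = 0, scatter = 0, skipped = 0),
      edep_mev = dose * 0
    ),
    class = "dose_grid"
  )
}

gaussian_ball_dose <- function(n = 41, spacing = 0.1, sigma = 0.5) {
  cc <- ((seq_len(n)) - (n + 1) / 2) * spacing
  r2 <- outer(outer(cc^2, cc^2, "+"), cc^2, "+")
  make_dose_grid(exp(-r2 / (2 * sigma^2)), spacing = spacing)
}

uniform_field_map <- function(b_tesla = 1, half = 5, spacing = 1) {
  n <- 2 * half / spacing + 1
  B <- array(0, c(n, n, n, 3))
  B[, , , 2] <- b_tesla
  field_map(origin = rep(-half, 3), spacing = spacing, B = B)
}

electron_state <- function(x = 0, y = 0, z = 0, u = 0, v = 0, w = 1,
                           energy_mev = 6) {
  tibble::tibble(x = x, y = y, z = z, u = u, v = v, w = w,
    energy_mev = energy_mev, charge = -1)
}

random_phase_space <- function(n, seed = 1) {
  withr::with_seed(seed, {
    d <- matrix(rnorm(3 * n), n, 3)
    d <- d / sqrt(rowSums(d^2))
    rec <- tibble::tibble(
      kpar = sample(c(1L, 2L, 3L), n, replace = TRUE),
      energy_mev = runif(n, 0.05, 6),
      x = rnorm(n), y = rnorm(n), z = rnorm(n),
      u = d[, 1], v = d[, 2], w = d[, 3]
    )
    cxbeam:::new_phase_space(rec, n_primaries = n, exit_plane_z = -21)
  })
}

# static emission from the default device, small scale
small_emission <- function(n = 2e4, diameter_mm = 10, seed = 123,
                           spot = 0.3) {
  beam <- beam_spec(spot = spot, n_histories = n)
  prim <- sample_primaries(beam, n, seed = seed)
  geom <- convergent_geometry()
  coll <- collimator_spec(diameter_mm, 100)
  fr <- cxbeam:::device_frame(geom, 0.2, coll)
  hits <- cxbeam:::guide_to_target(prim, fr)
  emit_phase_space(hits, target_spec(), coll, geom, seed = seed + 1)
}
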