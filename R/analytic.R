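#' Convergent-beam geometry
#'
#' Describes the cone geometry of a convergent photon beam: a source ring of
#' radius `h` at axial standoff `L` from the focus, so the convergence
#' half-angle is `phi = atan(h / L)`.  The transversal beam area at depth `z`
#' below the entrance surface shrinks as `A(z) = A(0) (1 - z/F)^2`, with
#' `A(0) = pi r0^2` and focal depth `F`.  An optional `focal_spot` fraction
#' `delta` regularises the area as `A0 ((1 - z/F)^2 + delta^2)`, modelling a
#' finite focal-spot size; the default `delta = 0` is the pure geometric law.
#'
#' @param L Source-ring axial standoff from the focus, cm.
#' @param h Source-ring (lateral) radius, cm.
#' @param focal_depth Depth of the convergence point below the entrance
#'   surface, cm.  Defaults to `L` (entrance surface at the ring plane).
#' @param r0 Beam radius at the entrance surface, cm.  Defaults to `h`.
#' @param focal_spot Focal-spot radius as a fraction of `r0` (dimensionless
#'   `delta` above); default 0.
#' @return An object of class `convergent_geometry`.
#' @examples
#' geom <- convergent_geometry(L = 30, h = 10)
#' transversal_area(geom, 15)
#' @export
convergent_geometry <- function(L = 30, h = 10, focal_depth = L, r0 = h,
                                focal_spot = 0) {
  stopifnot(L > 0, h > 0, focal_depth > 0, r0 > 0, focal_spot >= 0)
  structure(
    list(
      L = L, h = h, focal_depth = focal_depth, r0 = r0,
      phi = atan2(h, L), focal_spot = focal_spot
    ),
    class = "convergent_geometry"
  )
}

#' @export
print.convergent_geometry <- function(x, ...) {
  cat(sprintf(
    "<convergent_geometry> L = %g cm, h = %g cm, F = %g cm, r0 = %g cm, phi = %.2f deg\n",
    x$L, x$h, x$focal_depth, x$r0, x$phi * 180 / pi
  ))
  invisible(x)
}

#' Transversal beam area at depth
#'
#' `A(z) = A(0) (1 - z/F)^2` with `A(0) = pi r0^2`; strictly decreasing on
#' `[0, F)` and degenerate (zero area) at the focal depth, where the
#' closed-form dose law diverges.
#'
#' @param geom A [convergent_geometry()].
#' @param z Depths in cm, `0 <= z < F`.
#' @return Areas in cm^2.
#' @export
transversal_area <- function(geom, z) {
  stopifnot(inherits(geom, "convergent_geometry"))
  f <- geom$focal_depth
  if (any(z < 0)) abort("Depth `z` must be non-negative.")
  if (any(z >= f) && geom$focal_spot == 0) {
    abort(sprintf(
      "Degenerate geometry: depth z >= focal depth F = %g cm (transversal area reaches 0 and the dose law diverges).",
      f
    ))
  }
  pi * geom$r0^2 * ((1 - z / f)^2 + geom$focal_spot^2)
}

#' Photon spectrum container
#'
#' A discrete energy spectrum: bin energies in MeV with non-negative
#' probability weights summing to one.  A mono-energetic beam is a single bin.
#'
#' @param energies Bin energies, MeV.
#' @param weights Bin probabilities; normalised if they do not sum to one.
#' @return A tibble of class `beam_spectrum` with columns `energy_mev`,
#'   `weight`.
#' @export
beam_spectrum <- function(energies, weights = rep(1, length(energies))) {
  stopifnot(length(energies) == length(weights), length(energies) >= 1L)
  if (any(weights < 0)) abort("Spectrum weights must be non-negative.")
  s <- sum(weights)
  if (s <= 0) abort("Spectrum weights must not all be zero.")
  out <- tibble(energy_mev = as.numeric(energies), weight = weights / s)
  class(out) <- c("beam_spectrum", class(out))
  out
}

#' On-axis depth dose of a convergent beam
#'
#' Closed-form primary-beam dose at depth `z`:
#' \deqn{D(z) = D_0 \left(\frac{A(0)}{A(z)}\right)^{p}
#'   \sum_E w_E \, e^{-\mu(E)\,\rho\, z \sec\varphi}}
#' with area-ratio exponent `p = 2` as printed in the source law (a
#' `area_exponent = 1` switch gives plain fluence conservation), and the path
#' length along the oblique ray `s(z) = z sec(phi)`; the full-depth path is
#' `h sec(phi)` measured from the ring.  Poly-energetic spectra are handled
#' as a weighted sum of mono-energetic attenuation terms.
#'
#' @inheritParams transversal_area
#' @param spectrum A [beam_spectrum()].
#' @param medium Material label for the attenuating medium.
#' @param density Medium density in g/cm^3.
#' @param D0 Entrance (surface) dose, Gy.
#' @param area_exponent Exponent on the focusing area ratio; 2 as printed.
#' @param attenuation Set `FALSE` to disable attenuation (pure focusing).
#' @return Dose in Gy, vectorised over `z`.
#' @examples
#' geom <- convergent_geometry(L = 30, h = 10)
#' mono <- beam_spectrum(1.25)
#' on_axis_dose(geom, mono, "water", 1.0, z = c(0, 10, 20))
#' @export
on_axis_dose <- function(geom, spectrum, medium, density, z, D0 = 1,
                         area_exponent = 2, attenuation = TRUE) {
  stopifnot(inherits(geom, "convergent_geometry"))
  if (!inherits(spectrum, "beam_spectrum") || nrow(spectrum) == 0L) {
    abort("`spectrum` must be a non-empty beam_spectrum.")
  }
  a0 <- pi * geom$r0^2 * (1 + geom$focal_spot^2)
  az <- transversal_area(geom, z)
  focus <- (a0 / az)^area_exponent
  if (!attenuation) {
    return(D0 * focus)
  }
  sec_phi <- 1 / cos(geom$phi)
  mu <- mu_over_rho(medium, spectrum$energy_mev) * density
  att <- vapply(
    z,
    function(zi) sum(spectrum$weight * exp(-mu * zi * sec_phi)),
    numeric(1)
  )
  D0 * focus * att
}

# single shifted peak used for spread-out synthesis: same area law, extended
# symmetrically past the focal depth (the cone re-opens beyond its apex)
psop_peak <- function(geom, focal_depth, spectrum, medium, density, z) {
  g <- geom
  g$focal_depth <- focal_depth
  a0 <- pi * g$r0^2 * (1 + g$focal_spot^2)
  az <- pi * g$r0^2 * ((1 - z / focal_depth)^2 + g$focal_spot^2)
  if (g$focal_spot == 0 && any(az == 0)) {
    abort("Peak evaluated at its focal depth with a zero focal spot; set `focal_spot` > 0.")
  }
  sec_phi <- 1 / cos(g$phi)
  mu <- mu_over_rho(medium, spectrum$energy_mev) * density
  att <- vapply(
    z,
    function(zi) sum(spectrum$weight * exp(-mu * zi * sec_phi)),
    numeric(1)
  )
  (a0 / az)^2 * att
}

#' Photon spread-out peak profile
#'
#' Superposes convergent-beam peaks with focal depths scanned over
#' `scan_depths`, weighted by `weights`, to emulate the longitudinal scan
#' that produces a spread-out dose plateau (the photon analogue of a
#' spread-out Bragg peak).  The profile is normalised to a maximum of 1.
#'
#' @inheritParams on_axis_dose
#' @param scan_depths Focal depths of the superposed peaks, cm.
#' @param weights Non-negative peak weights, same length as `scan_depths`.
#' @param z_grid Depths at which to evaluate the profile, cm.
#' @return A tibble of class `psop_profile` with columns `z_cm`, `dose`.
#' @export
psop_profile <- function(geom, scan_depths, weights, spectrum, medium,
                         density, z_grid) {
  if (length(scan_depths) != length(weights)) {
    abort("`scan_depths` and `weights` must have the same length.")
  }
  if (any(weights < 0)) abort("Peak weights must be non-negative.")
  dose <- rep(0, length(z_grid))
  for (i in seq_along(scan_depths)) {
    dose <- dose + weights[i] *
      psop_peak(geom, scan_depths[i], spectrum, medium, density, z_grid)
  }
  m <- max(dose)
  if (m <= 0) abort("Spread-out profile is identically zero.")
  out <- tibble(z_cm = z_grid, dose = dose / m)
  class(out) <- c("psop_profile", class(out))
  attr(out, "scan_depths") <- scan_depths
  attr(out, "weights") <- weights
  out
}

#' Peak weights that flatten the spread-out plateau
#'
#' Solves a non-negative least-squares problem for the peak weights that make
#' the superposed profile closest to a constant over the plateau interval.
#' Deterministic given its inputs.
#'
#' @inheritParams psop_profile
#' @param plateau Two-vector `c(z_lo, z_hi)` inside the scanned depth range.
#' @param n_grid Number of plateau evaluation points for the fit.
#' @return Non-negative weights, normalised to sum to one.
#' @export
flatten_weights <- function(geom, scan_depths, spectrum, medium, density,
                            plateau, n_grid = 101L) {
  if (length(scan_depths) < 1L) abort("At least one scan depth is required.")
  if (length(scan_depths) == 1L) {
    return(1.0)
  }
  rng <- range(scan_depths)
  if (plateau[1] >= plateau[2] || plateau[1] < rng[1] - 1e-9 ||
    plateau[2] > rng[2] + 1e-9) {
    abort("`plateau` must be an increasing interval inside the scanned depth range.")
  }
  zg <- seq(plateau[1], plateau[2], length.out = n_grid)
  basis <- vapply(
    scan_depths,
    function(f) psop_peak(geom, f, spectrum, medium, density, zg),
    numeric(length(zg))
  )
  # scale columns so the NNLS problem is well conditioned
  colscale <- apply(basis, 2, max)
  w <- pracma::lsqnonneg(sweep(basis, 2, colscale, "/"), rep(1, length(zg)))$x
  w <- w / colscale
  if (sum(w) <= 0) abort("Flattening produced an all-zero weight vector.")
  w / sum(w)
}
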