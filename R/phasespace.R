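KPAR_CODES <- c(electron = 1L, photon = 2L, positron = 3L)

#' Bremsstrahlung target and photon collimator specifications
#'
#' The photon production target is a thin high-Z disc (by default 1.15 mm of
#' tungsten); setting `present = FALSE` removes it, switching the device to
#' electron mode.  The emerging-beam collimator is a cylindrical tungsten
#' bore whose diameter and length select the collimation configuration
#' (typical diameters 3-30 mm, lengths 80-120 mm).
#'
#' @param material Target/collimator material label.
#' @param thickness_mm Target thickness, mm.
#' @param present Is the target in the beam? `FALSE` = electron mode.
#' @return A `target_spec` object.
#' @export
target_spec <- function(material = "tungsten", thickness_mm = 1.15,
                        present = TRUE) {
  if (present) stopifnot(thickness_mm > 0)
  structure(
    list(material = match_material(material), thickness_mm = thickness_mm,
      present = isTRUE(present)),
    class = "target_spec"
  )
}

#' @rdname target_spec
#' @param diameter_mm Bore diameter, mm.
#' @param length_mm Bore length, mm.
#' @export
collimator_spec <- function(diameter_mm = 10, length_mm = 100,
                            material = "tungsten") {
  stopifnot(diameter_mm > 0, diameter_mm <= 50, length_mm > 0)
  structure(
    list(diameter_mm = diameter_mm, length_mm = length_mm,
      material = match_material(material)),
    class = "collimator_spec"
  )
}

#' Thick-target bremsstrahlung spectrum
#'
#' Parametrised thick-target model: a Kramers-shaped intensity
#' `N(E) ~ (E0 - E) / E` hardened by self-filtration through half the target
#' thickness, `exp(-mu_W(E) rho_W t/2)`, truncated to `[e_min, E0]` and
#' renormalised.  Characteristic K-lines are negligible at MV energies and
#' are off by default.
#'
#' @param e0_mev Electron kinetic energy (spectrum end point), MeV.
#' @param target A [target_spec()].
#' @param e_min_mev Low-energy cutoff, MeV.
#' @param n_bins Number of spectrum bins.
#' @return A [beam_spectrum()] whose rows are bin midpoints; bin edges are
#'   kept as an attribute so [sample_spectrum()] can jitter within bins.
#' @export
brems_spectrum <- function(e0_mev, target = target_spec(),
                           e_min_mev = 0.05, n_bins = 400L) {
  tab <- material_table(target$material)
  if (e0_mev <= e_min_mev) abort("`e0_mev` must exceed the spectrum cutoff.")
  if (e0_mev > max(tab$energy_mev)) {
    abort("`e0_mev` above the tabulated coefficient span.")
  }
  edges <- seq(e_min_mev, e0_mev, length.out = n_bins + 1L)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  rho <- material_density(target$material)
  t_half <- target$thickness_mm / 10 / 2 # cm
  filt <- exp(-mu_over_rho(target$material, mid) * rho * t_half)
  w <- (e0_mev - mid) / mid * filt * diff(edges)
  spec <- beam_spectrum(mid, w)
  attr(spec, "edges") <- edges
  attr(spec, "e0_mev") <- e0_mev
  spec
}

#' Sample photon energies from a spectrum
#'
#' Bin-weighted sampling; for binned spectra (those carrying bin edges, as
#' produced by [brems_spectrum()]) the draw is jittered uniformly within the
#' bin so the sampled distribution is continuous.
#'
#' @param spectrum A [beam_spectrum()].
#' @param n Number of draws.
#' @param seed Optional seed.
#' @return Energies in MeV.
#' @export
sample_spectrum <- function(spectrum, n, seed = NULL) {
  with_seed(seed, {
    i <- sample.int(nrow(spectrum), n, replace = TRUE,
      prob = spectrum$weight)
    edges <- attr(spectrum, "edges")
    if (is.null(edges)) {
      spectrum$energy_mev[i]
    } else {
      edges[i] + runif(n) * (edges[i + 1L] - edges[i])
    }
  })
}

device_frame <- function(geom, gap_cm, collimator) {
  src <- c(geom$h, 0, -geom$L) # static target position on the ring
  b <- transverse_basis(-src / sqrt(sum(src^2))) # axis aims at the focus
  list(
    source = src, axis = b$axis, t1 = b$t1, t2 = b$t2,
    entrance = src + gap_cm * b$axis,
    exit = src + (gap_cm + collimator$length_mm / 10) * b$axis,
    r_bore = collimator$diameter_mm / 20
  )
}

#' Generate the emerging phase space at the target/collimator stage
#'
#' Electrons striking the target radiate bremsstrahlung photons sampled from
#' [brems_spectrum()] with a forward-peaked Gaussian angular kernel of
#' characteristic angle `m_e c^2 / E0` about the bore axis.  Only photons
#' whose straight-line path clears both apertures of the collimator bore are
#' emitted; survivors are scored on the plane `z = exit_plane_z`.  With the
#' target removed (`target$present = FALSE`) the electrons themselves are
#' passed through the collimator acceptance unchanged (electron mode).
#'
#' @param electron_hits Tibble of electron states on the target
#'   (columns `x,y,z,u,v,w,energy_mev`).
#' @param target A [target_spec()].
#' @param collimator A [collimator_spec()].
#' @param geom A [convergent_geometry()] placing the target ring; the bore
#'   axis points from the static target position to the focus (origin).
#' @param exit_plane_z Scoring plane, cm (default -21).
#' @param n_photons_per_electron Mean photons radiated per electron into the
#'   modelled part of the spectrum (Poisson-distributed per electron).
#' @param gap_cm Distance from target to the bore entrance, cm.
#' @param seed Seed for the emission sampling.
#' @return A phase-space tibble (class `phase_space`) with columns
#'   `kpar, energy_mev, x, y, z, u, v, w` and attributes `n_primaries`,
#'   `exit_plane_z`.
#' @export
emit_phase_space <- function(electron_hits, target = target_spec(),
                             collimator = collimator_spec(),
                             geom = convergent_geometry(),
                             exit_plane_z = -21,
                             n_photons_per_electron = 3,
                             gap_cm = 0.2, seed = NULL) {
  n_el <- nrow(electron_hits)
  if (n_el == 0L) abort("`electron_hits` is empty.")
  fr <- device_frame(geom, gap_cm, collimator)
  with_seed(seed, {
    if (target$present) {
      k <- stats::rpois(n_el, n_photons_per_electron)
      idx <- rep.int(seq_len(n_el), k)
      np <- length(idx)
      if (np == 0L) {
        return(empty_phase_space(n_el, exit_plane_z))
      }
      e0 <- mean(electron_hits$energy_mev)
      spec <- brems_spectrum(e0, target)
      en <- sample_spectrum(spec, np)
      sig_theta <- ELECTRON_MC2 / e0
      ta <- rnorm(np, 0, sig_theta)
      tb <- rnorm(np, 0, sig_theta)
      dir <- unit_rows(
        matrix(fr$axis, np, 3, byrow = TRUE) +
          outer(ta, fr$t1) + outer(tb, fr$t2)
      )
      pos <- cbind(electron_hits$x[idx], electron_hits$y[idx],
        electron_hits$z[idx])
      kpar <- rep(KPAR_CODES[["photon"]], np)
    } else {
      pos <- cbind(electron_hits$x, electron_hits$y, electron_hits$z)
      dir <- cbind(electron_hits$u, electron_hits$v, electron_hits$w)
      en <- electron_hits$energy_mev
      kpar <- rep(KPAR_CODES[["electron"]], n_el)
    }
    # collimator acceptance: the ray must be inside the bore radius at both
    # aperture planes (the radial offset is convex along a straight ray)
    ok <- rep(TRUE, length(en))
    d_ax <- as.vector(dir %*% fr$axis)
    for (plane in list(fr$entrance, fr$exit)) {
      tplane <- ((plane[1] - pos[, 1]) * fr$axis[1] +
        (plane[2] - pos[, 2]) * fr$axis[2] +
        (plane[3] - pos[, 3]) * fr$axis[3]) / d_ax
      q <- pos + dir * tplane
      relq <- sweep(q, 2, plane)
      ok <- ok & d_ax > 0 & rowSums(relq^2) <= fr$r_bore^2
    }
    pos <- pos[ok, , drop = FALSE]
    dir <- dir[ok, , drop = FALSE]
    en <- en[ok]
    kpar <- kpar[ok]
    if (length(en) == 0L) {
      return(empty_phase_space(n_el, exit_plane_z))
    }
    tz <- (exit_plane_z - pos[, 3]) / dir[, 3]
    rec <- tibble(
      kpar = as.integer(kpar), energy_mev = en,
      x = pos[, 1] + tz * dir[, 1], y = pos[, 2] + tz * dir[, 2],
      z = rep(exit_plane_z, length(en)),
      u = dir[, 1], v = dir[, 2], w = dir[, 3]
    )
    new_phase_space(rec, n_primaries = n_el, exit_plane_z = exit_plane_z)
  })
}

new_phase_space <- function(rec, n_primaries, exit_plane_z = NA_real_) {
  class(rec) <- unique(c("phase_space", class(rec)))
  attr(rec, "n_primaries") <- n_primaries
  attr(rec, "exit_plane_z") <- exit_plane_z
  rec
}

empty_phase_space <- function(n_primaries, exit_plane_z) {
  new_phase_space(
    tibble(
      kpar = integer(), energy_mev = numeric(), x = numeric(),
      y = numeric(), z = numeric(), u = numeric(), v = numeric(),
      w = numeric()
    ),
    n_primaries = n_primaries, exit_plane_z = exit_plane_z
  )
}

validate_phase_space <- function(rec, norm_tol = 1e-4, where = NULL) {
  norm <- rec$u^2 + rec$v^2 + rec$w^2
  bad <- which(abs(norm - 1) > norm_tol)
  if (length(bad)) {
    abort(sprintf(
      "Direction-cosine norm violation (> %g) in %d record(s)%s, first at record %d (u2+v2+w2 = %.6g).",
      norm_tol, length(bad),
      if (is.null(where)) "" else paste0(" of ", where), bad[1], norm[bad[1]]
    ))
  }
  if (any(rec$energy_mev <= 0)) abort("Phase-space energies must be > 0.")
  if (!all(rec$kpar %in% KPAR_CODES)) {
    abort(sprintf(
      "Unknown particle code; expected one of {%s}.",
      paste(sprintf("%s=%d", names(KPAR_CODES), KPAR_CODES), collapse = ", ")
    ))
  }
  invisible(rec)
}

#' Read and write ASCII phase-space files
#'
#' One row per emerging particle, whitespace-delimited columns
#' `KPAR E[MeV] x[cm] y[cm] z[cm] u v w`, with `#`-prefixed header lines
#' recording the format version, the particle-code convention
#' (electron = 1, photon = 2, positron = 3) and the scoring-plane z.
#' Values are written with 17 significant digits so that
#' `read_phsp(write_phsp(r))` reproduces `r` exactly.
#'
#' @param records A phase-space tibble.
#' @param path File path.
#' @return `read_phsp()` returns the phase-space tibble; `write_phsp()`
#'   returns `path` invisibly.
#' @export
write_phsp <- function(records, path) {
  validate_phase_space(records)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# cxbeam phase-space format 1",
    "# kpar convention: electron=1 photon=2 positron=3",
    sprintf("# exit_plane_z_cm: %.17g", attr(records, "exit_plane_z") %||% NA),
    sprintf("# n_primaries: %.17g", attr(records, "n_primaries") %||% NA),
    "# columns: KPAR E[MeV] x[cm] y[cm] z[cm] u v w"
  ), con)
  body <- sprintf(
    "%d %.17g %.17g %.17g %.17g %.17g %.17g %.17g",
    records$kpar, records$energy_mev, records$x, records$y, records$z,
    records$u, records$v, records$w
  )
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_phsp
#' @param validate Check direction-cosine norms and particle codes on read.
#' @export
read_phsp <- function(path, validate = TRUE) {
  lines <- readLines(path)
  is_header <- grepl("^\\s*#", lines) | !nzchar(trimws(lines))
  body_idx <- which(!is_header)
  fields <- strsplit(trimws(lines[body_idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 8L)) {
    bad <- body_idx[which(nf != 8L)[1]]
    abort(sprintf(
      "Malformed phase-space row at line %d of '%s': expected 8 columns, found %d.",
      bad, path, nf[which(nf != 8L)[1]]
    ))
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = 8L, byrow = TRUE)
  if (anyNA(m)) {
    bad <- body_idx[which(rowSums(is.na(m)) > 0)[1]]
    abort(sprintf("Non-numeric field at line %d of '%s'.", bad, path))
  }
  hdr <- lines[grepl("^\\s*#", lines)]
  get_hdr <- function(key) {
    ln <- grep(key, hdr, value = TRUE)
    if (length(ln)) as.numeric(sub(paste0(".*", key, ":\\s*"), "", ln[1])) else NA_real_
  }
  rec <- new_phase_space(
    tibble(
      kpar = as.integer(m[, 1]), energy_mev = m[, 2],
      x = m[, 3], y = m[, 4], z = m[, 5],
      u = m[, 6], v = m[, 7], w = m[, 8]
    ),
    n_primaries = get_hdr("n_primaries"),
    exit_plane_z = get_hdr("exit_plane_z_cm")
  )
  if (validate) validate_phase_space(rec, where = path)
  rec
}

#' Rotate a phase space about a coordinate axis
#'
#' Positions and direction cosines are co-rotated.
#'
#' @param records Phase-space tibble.
#' @param angle_deg Rotation angle, degrees.
#' @param axis `"z"` (the convergence/turn axis) or `"x"` (the gantry axis).
#' @return The rotated phase space.
#' @export
rotate_phase_space <- function(records, angle_deg, axis = c("z", "x")) {
  axis <- match.arg(axis)
  a <- angle_deg * pi / 180
  ca <- cos(a)
  sa <- sin(a)
  out <- records
  if (axis == "z") {
    out$x <- ca * records$x - sa * records$y
    out$y <- sa * records$x + ca * records$y
    out$u <- ca * records$u - sa * records$v
    out$v <- sa * records$u + ca * records$v
  } else {
    out$y <- ca * records$y - sa * records$z
    out$z <- sa * records$y + ca * records$z
    out$v <- ca * records$v - sa * records$w
    out$w <- sa * records$v + ca * records$w
  }
  out
}

#' Integrate the static phase space over a full device turn
#'
#' The dynamic operation mode rotates the device about the convergence (+z)
#' axis; a full 360-degree turn is emulated by the union of the static phase
#' space rotated to `n_steps` equally spaced angles.  The output holds
#' `n_steps` times the input records, and its effective primary count scales
#' accordingly.
#'
#' @param records Static phase-space tibble.
#' @param n_steps Number of angular steps over 360 degrees (default 360).
#' @return The turn-integrated phase space.
#' @export
integrate_turn <- function(records, n_steps = 360L) {
  stopifnot(n_steps >= 1)
  n_steps <- as.integer(n_steps)
  parts <- lapply(seq_len(n_steps) - 1L, function(k) {
    rotate_phase_space(records, 360 * k / n_steps, axis = "z")
  })
  out <- dplyr::bind_rows(parts)
  new_phase_space(
    out,
    n_primaries = (attr(records, "n_primaries") %||% nrow(records)) * n_steps,
    exit_plane_z = attr(records, "exit_plane_z")
  )
}

#' Phase-space diagnostics
#'
#' Histograms of the phase-state variables: the energy spectrum, the spatial
#' marginals (x, y, z), the direction-cosine marginals (u, v, w) and the
#' production count per particle type.
#'
#' @param records Phase-space tibble.
#' @param n_bins Bins per histogram.
#' @return A list of tibbles (class `phsp_summary`): `$spectrum`,
#'   `$position`, `$direction`, `$particles`.
#' @export
phsp_diagnostics <- function(records, n_bins = 100L) {
  if (nrow(records) == 0L) abort("Cannot summarise an empty phase space.")
  hist_tbl <- function(x, var) {
    rng <- range(x)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    h <- graphics::hist(x, breaks = br, plot = FALSE)
    tibble(variable = var, mid = h$mids, count = h$counts)
  }
  out <- list(
    spectrum = hist_tbl(records$energy_mev, "energy_mev"),
    position = dplyr::bind_rows(
      hist_tbl(records$x, "x"), hist_tbl(records$y, "y"),
      hist_tbl(records$z, "z")
    ),
    direction = dplyr::bind_rows(
      hist_tbl(records$u, "u"), hist_tbl(records$v, "v"),
      hist_tbl(records$w, "w")
    ),
    particles = dplyr::count(
      tibble(particle = names(KPAR_CODES)[match(records$kpar, KPAR_CODES)]),
      .data$particle, name = "count"
    )
  )
  class(out) <- "phsp_summary"
  attr(out, "n_records") <- nrow(records)
  out
}
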