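ELECTRON_MC2 <- 0.51099895 # MeV

#' Primary electron beam specification
#'
#' Gaussian beam model for the primary electrons: kinetic energy
#' `mean_energy` with `fwhm_energy` spread, mean propagation tilt
#' `alpha_beam` (degrees, in the x-z plane) with angular spread `fwhm_alpha`,
#' and a transverse Gaussian spot of standard deviation `spot` (cm).  A zero
#' FWHM means a delta distribution (the filiform reference beam).
#'
#' The default spot (`sigma` = 0.3 cm) fills the 10 mm diameter guidance
#' canal of the beam line (about 3.3 sigma across the bore).
#'
#' @param mean_energy Mean kinetic energy, MeV (default 6.0).
#' @param fwhm_energy FWHM of the kinetic energy, MeV (default 0.1).
#' @param alpha_beam Mean tilt of propagation versus the optical axis, deg.
#' @param fwhm_alpha FWHM of the tilt distribution, deg.
#' @param spot Transverse Gaussian sigma, cm.
#' @param n_histories Default number of primary histories for pipeline runs.
#' @param seed Integer seed for reproducible sampling.
#' @return An object of class `beam_spec`.
#' @export
beam_spec <- function(mean_energy = 6.0, fwhm_energy = 0.1, alpha_beam = 0,
                      fwhm_alpha = 0, spot = 0.3, n_histories = 2e6,
                      seed = 1L) {
  stopifnot(
    mean_energy > 0, fwhm_energy >= 0, fwhm_alpha >= 0, spot >= 0,
    n_histories >= 1
  )
  structure(
    list(
      mean_energy = mean_energy, fwhm_energy = fwhm_energy,
      alpha_beam = alpha_beam, fwhm_alpha = fwhm_alpha, spot = spot,
      n_histories = n_histories, seed = as.integer(seed)
    ),
    class = "beam_spec"
  )
}

#' Sample primary electron states
#'
#' Draws `n` charged-particle states from a [beam_spec()]: energies from a
#' Gaussian truncated at zero, directions Gaussian-spread about the (tilted)
#' beam axis, transverse positions from the Gaussian spot at the start plane.
#' Bit-identical under a fixed seed.
#'
#' @param beam A [beam_spec()].
#' @param n Number of states to draw.
#' @param origin Start-plane centre, cm.
#' @param seed Seed override; defaults to `beam$seed`.
#' @return A tibble with columns `x, y, z` (cm), `u, v, w` (direction
#'   cosines), `energy_mev` and `charge` (in units of e).
#' @export
sample_primaries <- function(beam, n, origin = c(0, 0, 0), seed = beam$seed) {
  stopifnot(inherits(beam, "beam_spec"), n >= 1)
  with_seed(seed, {
    sig_e <- fwhm_to_sigma(beam$fwhm_energy)
    e <- if (sig_e == 0) {
      rep(beam$mean_energy, n)
    } else {
      ei <- rnorm(n, beam$mean_energy, sig_e)
      while (any(bad <- ei <= 0)) {
        ei[bad] <- rnorm(sum(bad), beam$mean_energy, sig_e)
      }
      ei
    }
    a0 <- beam$alpha_beam * pi / 180
    axis <- c(sin(a0), 0, cos(a0))
    sig_a <- fwhm_to_sigma(beam$fwhm_alpha) * pi / 180
    if (sig_a == 0) {
      dir <- matrix(axis, n, 3, byrow = TRUE)
    } else {
      b <- transverse_basis(axis)
      ta <- rnorm(n, 0, sig_a)
      tb <- rnorm(n, 0, sig_a)
      dir <- unit_rows(
        matrix(axis, n, 3, byrow = TRUE) +
          outer(ta, b$t1) + outer(tb, b$t2)
      )
    }
    sx <- if (beam$spot > 0) rnorm(n, 0, beam$spot) else rep(0, n)
    sy <- if (beam$spot > 0) rnorm(n, 0, beam$spot) else rep(0, n)
    tibble(
      x = origin[1] + sx, y = origin[2] + sy, z = rep(origin[3], n),
      u = dir[, 1], v = dir[, 2], w = dir[, 3],
      energy_mev = e, charge = rep(-1, n)
    )
  })
}

#' Voxelized magnetic-field map
#'
#' A regular 3D grid of field vectors (tesla).  The field is uniform within
#' each voxel; `origin` is the world coordinate of the first voxel centre.
#'
#' @param origin Centre of voxel (1,1,1), cm.
#' @param spacing Voxel spacing per axis, cm.
#' @param B A 4D array `[nx, ny, nz, 3]` of field components in tesla.
#' @return An object of class `field_map`.
#' @export
field_map <- function(origin, spacing, B) {
  stopifnot(length(dim(B)) == 4L, dim(B)[4] == 3L, all(is.finite(B)))
  spacing <- rep(spacing, length.out = 3)
  structure(
    list(origin = origin, spacing = spacing, dim = dim(B)[1:3], B = B),
    class = "field_map"
  )
}

#' Synthetic dipole deflection-magnet map
#'
#' Generates a voxelized dipole field pointing along +y: a central plateau at
#' `strength` with a smooth cosine fringe falling below `0.1 * strength` at
#' the map boundary, mirror-symmetric about each central plane.  Emulates the
#' measured central-plane maps of bench-characterised deflection magnets
#' (0.1-1 T span).
#'
#' @param strength Plateau field strength, tesla, in (0, 3].
#' @param pole_gap Gap between poles (y extent of the map), cm.
#' @param extent Transverse extent of the map (x and z), cm.
#' @param edge_softness Width of the fringe roll-off, cm.
#' @param spacing Voxel size, cm (millimetric by default).
#' @return A [field_map()].
#' @export
generate_dipole_map <- function(strength, pole_gap = 4, extent = 10,
                                edge_softness = 1.5, spacing = 0.1) {
  stopifnot(strength > 0, strength <= 3)
  half <- c(extent, pole_gap, extent) / 2
  nx <- 2L * as.integer(ceiling(half[1] / spacing)) + 1L
  ny <- 2L * as.integer(ceiling(half[2] / spacing)) + 1L
  nz <- 2L * as.integer(ceiling(half[3] / spacing)) + 1L
  cx <- seq(-(nx - 1) / 2, (nx - 1) / 2) * spacing
  cy <- seq(-(ny - 1) / 2, (ny - 1) / 2) * spacing
  cz <- seq(-(nz - 1) / 2, (nz - 1) / 2) * spacing
  roll <- function(t, h) {
    # 1 on the plateau, cosine roll-off over `edge_softness`, 0.01 floor
    plateau <- h - edge_softness
    f <- ifelse(
      abs(t) <= plateau, 1,
      0.5 * (1 + cos(pi * pmin((abs(t) - plateau) / edge_softness, 1)))
    )
    pmax(f, 0.01)
  }
  fx <- roll(cx, half[1])
  fy <- roll(cy, half[2])
  fz <- roll(cz, half[3])
  by <- strength * outer(outer(fx, fy), fz)
  B <- array(0, dim = c(nx, ny, nz, 3))
  B[, , , 2] <- by
  field_map(origin = c(cx[1], cy[1], cz[1]), spacing = spacing, B = B)
}

field_at <- function(field, p, mode = c("nearest", "trilinear")) {
  mode <- match.arg(mode)
  idx <- (p - field$origin) / field$spacing
  if (mode == "nearest") {
    i <- round(idx) + 1
    if (any(i < 1) || any(i > field$dim)) {
      return(NULL) # outside the tracking volume
    }
    field$B[i[1], i[2], i[3], ]
  } else {
    i0 <- floor(idx)
    f <- idx - i0
    i0 <- i0 + 1
    if (any(i0 < 1) || any(i0 + 1 > field$dim)) {
      return(NULL)
    }
    out <- numeric(3)
    for (k in 1:3) {
      c00 <- field$B[i0[1], i0[2], i0[3], k] * (1 - f[1]) +
        field$B[i0[1] + 1, i0[2], i0[3], k] * f[1]
      c10 <- field$B[i0[1], i0[2] + 1, i0[3], k] * (1 - f[1]) +
        field$B[i0[1] + 1, i0[2] + 1, i0[3], k] * f[1]
      c01 <- field$B[i0[1], i0[2], i0[3] + 1, k] * (1 - f[1]) +
        field$B[i0[1] + 1, i0[2], i0[3] + 1, k] * f[1]
      c11 <- field$B[i0[1], i0[2] + 1, i0[3] + 1, k] * (1 - f[1]) +
        field$B[i0[1] + 1, i0[2] + 1, i0[3] + 1, k] * f[1]
      out[k] <- (c00 * (1 - f[2]) + c10 * f[2]) * (1 - f[3]) +
        (c01 * (1 - f[2]) + c11 * f[2]) * f[3]
    }
    out
  }
}

#' Track a charged particle through a magnetic-field map
#'
#' Relativistic tracking with a volume-preserving rotation stepper in the
#' Boris family: at each step the direction is rotated about the local field
#' by the exact gyration angle and the position advances along the rotation
#' chord.  Magnetic forces do no work, so the kinetic energy is conserved
#' exactly; position accuracy is second order in the step.
#' Field lookup is nearest-voxel by default (uniform field within each
#' voxel), with an optional trilinear mode.
#'
#' The trajectory terminates on leaving the field-map volume, on hitting the
#' wall of an optional cylindrical canal, or at `max_length`.
#'
#' @param state One charged state: a 1-row tibble as returned by
#'   [sample_primaries()] (columns `x,y,z,u,v,w,energy_mev,charge`).
#' @param field A [field_map()].
#' @param step Step length, cm; should not exceed the field voxel spacing.
#' @param max_length Maximum path length, cm.
#' @param canal Optional canal: `list(diameter_mm=, length_mm=, origin=,
#'   axis=)`; the wall is checked while the particle is within the axial
#'   span of the canal.
#' @param lookup Field interpolation, `"nearest"` or `"trilinear"`.
#' @param outside Behaviour on leaving the field-map volume: `"stop"`
#'   (terminate, the default) or `"free"` (continue ballistically in a null
#'   field, e.g. to reach a canal placed beyond the map).
#' @return A tibble (class `trajectory`) with one row per step: `s` (path
#'   length), `x,y,z,u,v,w,energy_mev`; attribute `status` is one of
#'   `"exit_volume"`, `"wall"`, `"max_length"`.
#' @export
track <- function(state, field, step = 0.02, max_length = 50, canal = NULL,
                  lookup = c("nearest", "trilinear"),
                  outside = c("stop", "free")) {
  lookup <- match.arg(lookup)
  outside <- match.arg(outside)
  stopifnot(inherits(field, "field_map"), step > 0, max_length > 0)
  if (step > min(field$spacing) + 1e-12) {
    warn("`step` exceeds the field voxel spacing; accuracy is not guaranteed.")
  }
  p <- c(state$x[1], state$y[1], state$z[1])
  d <- c(state$u[1], state$v[1], state$w[1])
  d <- d / sqrt(sum(d^2))
  e <- state$energy_mev[1]
  q <- state$charge[1]
  pc <- sqrt(e * (e + 2 * ELECTRON_MC2)) # MeV
  # gyroradius r[cm] = pc[MeV] / (2.99792458e-3 * 1000 * B[T])
  kappa <- q * 2.99792458 / pc # curvature (1/cm) per tesla
  n_max <- as.integer(ceiling(max_length / step)) + 1L
  out <- matrix(NA_real_, n_max + 1L, 8L)
  out[1L, ] <- c(0, p, d, e)
  status <- "max_length"
  canal_r <- NULL
  if (!is.null(canal)) {
    canal_r <- canal$diameter_mm / 20 # mm diameter -> cm radius
    canal_len <- canal$length_mm / 10
    cb <- transverse_basis(canal$axis %||% c(0, 0, 1))
    corg <- canal$origin %||% c(0, 0, 0)
  }
  s <- 0
  i <- 1L
  while (s < max_length - 1e-12) {
    ds <- min(step, max_length - s)
    bvec <- field_at(field, p, lookup)
    if (is.null(bvec)) {
      if (outside == "stop") {
        status <- "exit_volume"
        break
      }
      bvec <- c(0, 0, 0) # field-free ballistic continuation
    }
    # volume-preserving rotation step: rotate the direction about the local
    # field by the exact gyration angle (Rodrigues), then advance along the
    # chord; energy is untouched, position is second-order accurate
    bmag <- sqrt(sum(bvec^2))
    if (bmag > 0) {
      bh <- bvec / bmag
      ang <- -kappa * bmag * ds # d' = d + kappa ds (d x B) to first order
      ca <- cos(ang)
      sa <- sin(ang)
      bxd <- c(
        bh[2] * d[3] - bh[3] * d[2],
        bh[3] * d[1] - bh[1] * d[3],
        bh[1] * d[2] - bh[2] * d[1]
      )
      dn <- d * ca + bxd * sa + bh * sum(bh * d) * (1 - ca)
    } else {
      dn <- d
    }
    chord <- d + dn
    chord <- chord / sqrt(sum(chord^2))
    p <- p + chord * ds
    d <- dn
    s <- s + ds
    i <- i + 1L
    out[i, ] <- c(s, p, d, e)
    if (!is.null(canal_r)) {
      rel <- p - corg
      ax <- sum(rel * cb$axis)
      if (ax >= 0 && ax <= canal_len) {
        rad2 <- sum(rel^2) - ax^2
        if (rad2 > canal_r^2) {
          status <- "wall"
          break
        }
      }
    }
  }
  traj <- as_tibble(as.data.frame(out[seq_len(i), , drop = FALSE]))
  names(traj) <- c("s", "x", "y", "z", "u", "v", "w", "energy_mev")
  class(traj) <- c("trajectory", class(traj))
  attr(traj, "status") <- status
  traj
}

#' Fraction of trajectories transmitted through a cylindrical canal
#'
#' Counts the trajectories that reach the canal exit plane without ever
#' violating the wall while inside the canal's axial span.
#'
#' @param trajectories A list of [track()] outputs.
#' @param canal_diameter_mm Canal bore diameter, mm.
#' @param canal_length_mm Canal length, mm.
#' @param canal_origin Canal entrance centre, cm.
#' @param canal_axis Canal axis direction (normalised internally).
#' @return Transmission fraction in `[0, 1]`.
#' @export
transmission_fraction <- function(trajectories, canal_diameter_mm,
                                  canal_length_mm,
                                  canal_origin = c(0, 0, 0),
                                  canal_axis = c(0, 0, 1)) {
  if (length(trajectories) == 0L) abort("No trajectories supplied.")
  r <- canal_diameter_mm / 20
  len <- canal_length_mm / 10
  cb <- transverse_basis(canal_axis)
  ok <- vapply(trajectories, function(tr) {
    rel <- cbind(tr$x - canal_origin[1], tr$y - canal_origin[2],
      tr$z - canal_origin[3])
    ax <- rel %*% cb$axis
    rad2 <- rowSums(rel^2) - ax^2
    inside <- ax >= 0 & ax <= len
    if (any(inside & rad2 > r^2)) {
      return(FALSE)
    }
    max(ax) >= len
  }, logical(1))
  mean(ok)
}

#' Tune a dipole strength to a target deflection angle
#'
#' Deterministic bisection on the plateau strength of a
#' [generate_dipole_map()] so that a reference electron of the given energy,
#' entering along +z, leaves the map deflected by `target_angle_deg` in the
#' x-z plane.  Mirrors the practice of applying minor tilts/strength trims to
#' the deflection magnets when the beam energy changes.
#'
#' @param target_angle_deg Requested deflection, degrees.
#' @param energy_mev Electron kinetic energy, MeV.
#' @param start Entry point of the reference electron, cm.
#' @param bounds Strength search interval, tesla.
#' @param step Tracking step, cm.
#' @param tol Angle tolerance, degrees.
#' @param ... Passed to [generate_dipole_map()].
#' @return `list(strength=, field=, reference=)` with the tuned map and the
#'   reference trajectory.
#' @export
tune_dipole <- function(target_angle_deg, energy_mev = 6.0,
                        start = c(0, 0, -6), bounds = c(0.01, 3),
                        step = 0.05, tol = 0.01, ...) {
  ref_state <- tibble(
    x = start[1], y = start[2], z = start[3],
    u = 0, v = 0, w = 1, energy_mev = energy_mev, charge = -1
  )
  angle_for <- function(strength) {
    fm <- generate_dipole_map(strength, ...)
    tr <- track(ref_state, fm, step = step, max_length = 40,
      outside = "free")
    dlast <- c(tail(tr$u, 1), tail(tr$v, 1), tail(tr$w, 1))
    atan2(abs(dlast[1]), dlast[3]) * 180 / pi
  }
  lo <- bounds[1]
  hi <- bounds[2]
  if (angle_for(hi) < target_angle_deg) {
    abort("Target deflection not reachable within the strength bounds.")
  }
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    a <- angle_for(mid)
    if (abs(a - target_angle_deg) < tol) break
    if (a < target_angle_deg) lo <- mid else hi <- mid
  }
  fm <- generate_dipole_map(mid, ...)
  list(
    strength = mid, field = fm,
    reference = track(ref_state, fm, step = step, max_length = 40,
      outside = "free")
  )
}
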