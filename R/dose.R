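MEV_TO_J <- 1.602176634e-13

# internal accumulator so the pipeline can stream rotated phase-space chunks
# through the C++ tracer without materialising the full turn
new_kerma_accumulator <- function(phantom, n_batches = 20L) {
  nvox <- prod(phantom$dim)
  mats <- unique(as.vector(label_to_material[PHANTOM_LABELS[phantom$label]]))
  matidx <- array(
    match(label_to_material[PHANTOM_LABELS[phantom$label]], mats) - 1L,
    dim = phantom$dim
  )
  acc <- new.env(parent = emptyenv())
  acc$phantom <- phantom
  acc$materials <- mats
  acc$matidx <- matidx
  acc$n_batches <- as.integer(n_batches)
  acc$edep <- numeric(nvox)
  acc$edep_batch <- if (n_batches > 1L) numeric(nvox * n_batches) else numeric(0)
  acc$tallies <- c(entered = 0, escaped = 0, scatter = 0, skipped = 0)
  acc$boxmin <- phantom$origin - phantom$spacing / 2
  acc
}

mu_matrices <- function(acc, energy_mev) {
  list(
    mu = vapply(acc$materials, function(m) mu_over_rho(m, energy_mev),
      numeric(length(energy_mev))),
    muen = vapply(acc$materials, function(m) mu_en_over_rho(m, energy_mev),
      numeric(length(energy_mev)))
  )
}

accumulate_kerma <- function(acc, pos, dir, energy_mev, mu_row, batch,
                             mu, muen, tau_max = 40) {
  t <- kerma_trace_cpp(
    pos, dir, energy_mev, as.integer(mu_row), as.integer(batch),
    acc$n_batches, acc$boxmin, acc$phantom$spacing,
    as.integer(acc$phantom$dim), acc$matidx, acc$phantom$density,
    matrix(mu, ncol = length(acc$materials)),
    matrix(muen, ncol = length(acc$materials)),
    acc$edep, acc$edep_batch, tau_max
  )
  acc$tallies <- acc$tallies + t[c("entered", "escaped", "scatter", "skipped")]
  invisible(acc)
}

finalize_dose <- function(acc, n_histories) {
  ph <- acc$phantom
  voxvol <- prod(ph$spacing)
  mass_g <- ph$density * voxvol
  conv <- MEV_TO_J * 1000 # MeV per gram -> Gy
  dose <- array(acc$edep, dim = ph$dim) * conv
  dose <- ifelse(mass_g > 0, dose / mass_g, 0) / n_histories
  variance <- NULL
  if (acc$n_batches > 1L) {
    nb <- acc$n_batches
    bm <- matrix(acc$edep_batch, ncol = nb) # per-voxel per-batch energy
    conv_vox <- ifelse(mass_g > 0, conv / mass_g, 0)
    bdose <- bm * as.vector(conv_vox) / (n_histories / nb)
    mean_b <- rowMeans(bdose)
    variance <- array(
      rowSums((bdose - mean_b)^2) / (nb * (nb - 1)),
      dim = ph$dim
    )
  }
  structure(
    list(
      dose = array(dose, dim = ph$dim), variance = variance,
      n_histories = n_histories, origin = ph$origin, spacing = ph$spacing,
      dim = ph$dim, density = ph$density, tallies = acc$tallies,
      edep_mev = array(acc$edep, dim = ph$dim)
    ),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf(
    "<dose_grid> %d x %d x %d voxels, %g histories; max dose %.3e Gy/history\n",
    x$dim[1], x$dim[2], x$dim[3], x$n_histories, max(x$dose)
  ))
  invisible(x)
}

#' Deposit phase-space photons into a voxel phantom
#'
#' Primary-photon collision-kerma transport: each photon is ray-traced
#' through the voxel grid with exact boundary-crossing traversal; the energy
#' fluence is attenuated exponentially along the path and each voxel absorbs
#' the collision-kerma fraction `mu_en/mu` of the energy that interacts in
#' it.  Energy that interacts but is not locally absorbed (the scatter
#' surrogate) and energy that leaves the grid are tallied, so that
#' entering energy = deposited + scatter surrogate + escaped to numerical
#' precision.  Statistical uncertainty is estimated by the history-batch
#' method.
#'
#' @param records Phase-space tibble (photon records are transported;
#'   electron/positron records are not, and are counted as skipped).
#' @param phantom A [voxel_phantom()].
#' @param n_batches Batches for the variance estimate (default 20).
#' @param n_histories Number of primary histories the records represent;
#'   defaults to the phase space's `n_primaries` attribute.
#' @param tau_max Optical depth beyond which a ray is considered absorbed.
#' @return A `dose_grid`: dose (Gy per primary history) and per-voxel
#'   variance on the phantom grid, with energy-bookkeeping tallies.
#' @export
deposit <- function(records, phantom, n_batches = 20L,
                    n_histories = NULL, tau_max = 40) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  validate_phase_space(records)
  n_histories <- n_histories %||% attr(records, "n_primaries") %||%
    nrow(records)
  ph_rec <- records[records$kpar == KPAR_CODES[["photon"]], , drop = FALSE]
  n_skipped_particles <- nrow(records) - nrow(ph_rec)
  acc <- new_kerma_accumulator(phantom, n_batches)
  if (nrow(ph_rec) > 0L) {
    mm <- mu_matrices(acc, ph_rec$energy_mev)
    accumulate_kerma(
      acc,
      pos = cbind(ph_rec$x, ph_rec$y, ph_rec$z),
      dir = cbind(ph_rec$u, ph_rec$v, ph_rec$w),
      energy_mev = ph_rec$energy_mev,
      mu_row = seq_len(nrow(ph_rec)) - 1L,
      batch = (seq_len(nrow(ph_rec)) - 1L) %% n_batches,
      mu = mm$mu, muen = mm$muen, tau_max = tau_max
    )
  }
  out <- finalize_dose(acc, n_histories)
  out$tallies[["skipped"]] <- out$tallies[["skipped"]] + n_skipped_particles
  out
}

#' Voxel chord lengths along a ray
#'
#' Exact boundary-crossing traversal of one ray through a phantom grid;
#' used for validating the traversal against analytic chord lengths.
#'
#' @param phantom A [voxel_phantom()] or `dose_grid`.
#' @param origin Ray origin, cm.
#' @param direction Ray direction (normalised internally).
#' @return Tibble with voxel indices `ix, iy, iz` (1-based) and `length`
#'   (cm).
#' @export
voxel_path <- function(phantom, origin, direction) {
  direction <- direction / sqrt(sum(direction^2))
  res <- voxel_path_cpp(
    as.numeric(origin), as.numeric(direction),
    phantom$origin - phantom$spacing / 2, phantom$spacing,
    as.integer(phantom$dim)
  )
  as_tibble(res)
}

#' Mean dose in a sphere around the focal spot
#'
#' Mass-weighted mean dose over the voxels whose centres lie within `radius`
#' of `center` — the 1 cm focal-sphere figure of merit used for convergence
#' and uncertainty studies.
#'
#' @param dose A `dose_grid`.
#' @param center Sphere centre, cm (default the focus at the origin).
#' @param radius Sphere radius, cm.
#' @return Mean dose, Gy per primary history.
#' @export
dose_in_focal_sphere <- function(dose, center = c(0, 0, 0), radius = 1.0) {
  cc <- voxel_centers(dose)
  inside <- sphere_mask(cc, center, radius)
  if (!any(inside)) abort("No voxel centres inside the focal sphere.")
  w <- dose$density[inside]
  if (sum(w) <= 0) abort("Focal sphere has zero mass.")
  sum(dose$dose[inside] * w) / sum(w)
}

#' Statistical convergence study of the focal-sphere dose
#'
#' Runs the full simulation chain at each history count in `n_list` and at a
#' `reference_n`, and reports the percentage difference of the focal-sphere
#' dose with respect to the reference, together with the runtime fraction
#' `f_t`.  One reference run (with a seed derived from `seed`) is shared by
#' all repeats; each `(N, rep)` run gets its own derived seed.  With
#' repeats, medians over `rep` estimate the expected statistical deviation
#' at each N, which should fall off as 1/sqrt(N).
#'
#' @param config A [run_config()].
#' @param n_list History counts to study (each below `reference_n`).
#' @param reference_n Reference history count.
#' @param seed Master seed.
#' @param n_rep Independent repeats per N.
#' @return Tibble with columns `rep`, `n_histories`, `dose_focal`,
#'   `delta_pct`, `f_t`; the reference dose and runtime are attributes.
#' @export
convergence_study <- function(config, n_list, reference_n, seed = 1L,
                              n_rep = 1L) {
  if (any(n_list > reference_n)) {
    abort("All `n_list` entries must be at or below `reference_n`.")
  }
  run_at <- function(n, run_seed) {
    cfg <- config
    cfg$beam$n_histories <- n
    cfg$seed <- run_seed
    t0 <- proc.time()[["elapsed"]]
    res <- run_simulation(cfg, quiet = TRUE)
    list(
      dose = dose_in_focal_sphere(res$dose, radius = 1.0),
      time = proc.time()[["elapsed"]] - t0
    )
  }
  ref <- run_at(reference_n, derive_seed(seed, reference_n, 0))
  rows <- list()
  for (r in seq_len(n_rep) - 1L) {
    for (n in n_list) {
      this <- run_at(n, derive_seed(seed, n, r))
      rows[[length(rows) + 1L]] <- tibble(
        rep = r, n_histories = n, dose_focal = this$dose,
        delta_pct = abs(this$dose - ref$dose) / ref$dose * 100,
        f_t = this$time / ref$time
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "reference_n") <- reference_n
  attr(out, "reference_dose") <- ref$dose
  attr(out, "reference_time") <- ref$time
  out
}
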