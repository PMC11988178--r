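#' Cumulative dose-volume histogram
#'
#' For each dose level, the percentage of the structure's volume receiving
#' at least that dose, computed by voxel counting (volume-weighted; voxels
#' are congruent).  The curve is monotone non-increasing, starts at 100%
#' and ends at 0% just above the structure maximum.
#'
#' @param dose A `dose_grid`.
#' @param mask Logical array congruent with the grid (a structure mask), or
#'   `NULL` for the whole grid.
#' @param dose_axis Dose levels at which to evaluate the curve; default a
#'   512-point grid from 0 to just above the structure maximum.
#' @return A tibble of class `dvh_curve` with columns `dose` (Gy) and
#'   `volume_pct`.
#' @export
dvh <- function(dose, mask = NULL, dose_axis = NULL) {
  d <- if (is.null(mask)) as.vector(dose$dose) else dose$dose[mask]
  if (length(d) == 0L) abort("Empty structure mask.")
  dmax <- max(d)
  if (is.null(dose_axis)) {
    dose_axis <- seq(0, dmax * 1.001 + .Machine$double.eps, length.out = 512L)
  }
  vol <- vapply(dose_axis, function(t) mean(d >= t) * 100, numeric(1))
  out <- tibble(dose = dose_axis, volume_pct = vol)
  class(out) <- c("dvh_curve", class(out))
  attr(out, "n_voxels") <- length(d)
  out
}

isodose_mask <- function(dose, level_pct) {
  if (level_pct <= 0) {
    dose$dose > 0
  } else {
    dose$dose >= level_pct / 100 * max(dose$dose)
  }
}

#' Isodose volume and its largest connected component
#'
#' Volume of the voxels receiving at least `level_pct` percent of the
#' maximum dose (level 0 means the whole irradiated region, dose > 0), and
#' the largest 6-connected component of that region.
#'
#' @param dose A `dose_grid`.
#' @param level_pct Isodose level, percent of the maximum dose.
#' @return List with `volume_cm3`, `n_components`, `largest_volume_cm3` and
#'   `largest_mask` (logical array).
#' @export
isodose_volume <- function(dose, level_pct) {
  m <- isodose_mask(dose, level_pct)
  voxvol <- prod(dose$spacing)
  lab <- label_components6_cpp(as.vector(m), as.integer(dose$dim))
  ncomp <- attr(lab, "n_components")
  largest <- if (ncomp > 0) {
    counts <- tabulate(lab[lab > 0], nbins = ncomp)
    array(lab == which.max(counts), dim = dose$dim)
  } else {
    array(FALSE, dim = dose$dim)
  }
  list(
    volume_cm3 = sum(m) * voxvol,
    n_components = ncomp,
    largest_volume_cm3 = sum(largest) * voxvol,
    largest_mask = largest
  )
}

#' Mean extension of the 95% isodose volume
#'
#' The focal-spot size metric: the mean of the three orthogonal caliper
#' extents (bounding-box spans, voxel-centre to voxel-centre plus one voxel)
#' of the largest connected component of the >= 95% isodose region, in mm.
#' An alternative definition, the equivalent-sphere diameter of the same
#' component, is available via `method = "equivalent_sphere"`.
#'
#' @param dose A `dose_grid`.
#' @param level_pct Isodose level, default 95.
#' @param method `"caliper"` (default) or `"equivalent_sphere"`.
#' @return Extension in mm.
#' @export
mean_extension_95 <- function(dose, level_pct = 95,
                              method = c("caliper", "equivalent_sphere")) {
  method <- match.arg(method)
  if (max(dose$dose) <= 0) abort("Dose grid is identically zero.")
  comp <- isodose_volume(dose, level_pct)$largest_mask
  if (!any(comp)) abort("Empty isodose component.")
  if (method == "equivalent_sphere") {
    v <- sum(comp) * prod(dose$spacing)
    return((6 * v / pi)^(1 / 3) * 10)
  }
  idx <- which(comp, arr.ind = TRUE)
  spans <- vapply(1:3, function(a) {
    (max(idx[, a]) - min(idx[, a]) + 1) * dose$spacing[a]
  }, numeric(1))
  mean(spans) * 10
}

#' R50 surface (50% isodose contour)
#'
#' Boundary voxels of the >= 50%-of-maximum region: voxels in the region
#' with at least one 6-neighbour outside it (voxels on the grid edge count
#' as boundary).  For a uniform dose the whole grid is at 100% and the
#' contour is the grid's outer shell.
#'
#' @param dose A `dose_grid`.
#' @param level_pct Contour level, default 50.
#' @return Logical array marking the contour voxels.
#' @export
r50_surface <- function(dose, level_pct = 50) {
  m <- isodose_mask(dose, level_pct)
  dm <- dose$dim
  interior <- array(TRUE, dim = dm)
  shift_and <- function(acc, axis, by) {
    idx_src <- lapply(dm, seq_len)
    idx_dst <- idx_src
    n <- dm[axis]
    if (by > 0) {
      idx_dst[[axis]] <- seq_len(n - 1)
      idx_src[[axis]] <- 2:n
    } else {
      idx_dst[[axis]] <- 2:n
      idx_src[[axis]] <- seq_len(n - 1)
    }
    nb <- array(FALSE, dim = dm)
    nb[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    acc & nb
  }
  for (axis in 1:3) {
    interior <- shift_and(interior, axis, 1)
    interior <- shift_and(interior, axis, -1)
  }
  m & !interior
}
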