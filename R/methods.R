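#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_raster
#'   facet_wrap labs scale_fill_viridis_c coord_equal theme_minimal
#' @export
ggplot2::autoplot

#' Tidiers for simulation results
#'
#' `tidy()` returns the per-metric table of a run (or the curve of a DVH /
#' spread-out-peak profile, which are already tidy tibbles); `glance()`
#' returns a one-row summary.
#'
#' @param x A `cx_run`, `dose_grid`, `dvh_curve` or `psop_profile`.
#' @param ... Unused.
#' @name cxbeam-tidiers
NULL

#' @rdname cxbeam-tidiers
#' @export
tidy.cx_run <- function(x, ...) x$metrics

#' @rdname cxbeam-tidiers
#' @export
glance.cx_run <- function(x, ...) {
  out <- tidyr::pivot_wider(x$metrics, names_from = "metric",
    values_from = "value")
  dplyr::bind_cols(
    tibble(config_hash = x$config_hash, n_histories = x$dose$n_histories),
    out
  )
}

#' @rdname cxbeam-tidiers
#' @export
glance.dose_grid <- function(x, ...) {
  dep <- sum(x$edep_mev)
  tibble(
    n_histories = x$n_histories,
    max_dose = max(x$dose),
    energy_entered_mev = unname(x$tallies["entered"]),
    energy_deposited_mev = dep,
    energy_scatter_mev = unname(x$tallies["scatter"]),
    energy_escaped_mev = unname(x$tallies["escaped"]),
    rays_skipped = unname(x$tallies["skipped"])
  )
}

#' @rdname cxbeam-tidiers
#' @export
tidy.dose_grid <- function(x, ...) {
  cc <- voxel_centers(x)
  idx <- which(x$dose > 0, arr.ind = TRUE)
  tibble(
    x = cc$x[idx[, 1]], y = cc$y[idx[, 2]], z = cc$z[idx[, 3]],
    dose = x$dose[idx],
    rel_unc = if (!is.null(x$variance)) {
      sqrt(x$variance[idx]) / pmax(x$dose[idx], .Machine$double.xmin)
    } else {
      NA_real_
    }
  )
}

#' Plots for simulation results
#'
#' `autoplot()` methods: DVH curves, spread-out-peak depth profiles,
#' phase-space diagnostics and central-plane dose maps.
#'
#' @param object Object to plot.
#' @param ... Unused.
#' @name cxbeam-plots
NULL

#' @rdname cxbeam-plots
#' @export
autoplot.dvh_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$dose, y = .data$volume_pct)) +
    geom_line() +
    labs(x = "Dose [Gy]", y = "Volume receiving ≥ dose [%]") +
    theme_minimal()
}

#' @rdname cxbeam-plots
#' @export
autoplot.psop_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$z_cm, y = .data$dose)) +
    geom_line() +
    labs(x = "Depth z [cm]", y = "Normalised dose") +
    theme_minimal()
}

#' @rdname cxbeam-plots
#' @param which One of `"spectrum"`, `"position"`, `"direction"`.
#' @export
autoplot.phsp_summary <- function(object, which = "spectrum", ...) {
  d <- object[[which]]
  p <- ggplot(d, aes(x = .data$mid, y = .data$count)) +
    geom_col(width = diff(range(d$mid)) / 120) +
    labs(x = which, y = "Counts") +
    theme_minimal()
  if ("variable" %in% names(d)) {
    p <- p + facet_wrap(~variable, scales = "free_x")
  }
  p
}

#' @rdname cxbeam-plots
#' @param plane `"xy"`, `"xz"` or `"yz"` central plane through the dose
#'   maximum.
#' @export
autoplot.dose_grid <- function(object, plane = "xy", ...) {
  cc <- voxel_centers(object)
  imax <- which(object$dose == max(object$dose), arr.ind = TRUE)[1, ]
  sl <- switch(plane,
    xy = tidyr::expand_grid(b = cc$y, a = cc$x) |>
      dplyr::mutate(dose = as.vector(object$dose[, , imax[3]])),
    xz = tidyr::expand_grid(b = cc$z, a = cc$x) |>
      dplyr::mutate(dose = as.vector(object$dose[, imax[2], ])),
    yz = tidyr::expand_grid(b = cc$z, a = cc$y) |>
      dplyr::mutate(dose = as.vector(object$dose[imax[1], , ])),
    abort("`plane` must be one of 'xy', 'xz', 'yz'.")
  )
  lab <- strsplit(plane, "")[[1]]
  ggplot(sl, aes(x = .data$a, y = .data$b, fill = .data$dose)) +
    geom_raster() +
    scale_fill_viridis_c() +
    coord_equal() +
    labs(x = paste0(lab[1], " [cm]"), y = paste0(lab[2], " [cm]"),
      fill = "Gy/hist") +
    theme_minimal()
}
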