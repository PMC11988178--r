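#' Photon interaction data for the materials of the beam line
#'
#' The package embeds coarse (~26-point, log-spaced in energy) tables of the
#' mass attenuation coefficient \eqn{\mu/\rho} and the mass energy-absorption
#' coefficient \eqn{\mu_{en}/\rho} for the five materials the beam line and
#' the phantoms are built from: water (used for soft tissue), compact bone,
#' lung, air, and tungsten.  Values are transcribed from standard public
#' reference tables; the grids span 0.01--10 MeV and queries are interpolated
#' log-log, which is exact at the tabulated knots and standard practice for
#' photon cross sections.
#'
#' @param material Material label, one of [material_names()].
#' @return `material_table()` returns a tibble with columns `energy_mev`,
#'   `mu_over_rho`, `mu_en_over_rho` and attributes `material` and
#'   `default_density` (g/cm^3).
#' @examples
#' material_table("water")
#' mu_over_rho("water", 1.25)
#' @export
material_table <- function(material) {
  material <- match_material(material)
  if (is.null(the$materials)) the$materials <- list()
  if (!is.null(the$materials[[material]])) {
    return(the$materials[[material]])
  }
  path <- system.file("extdata", "materials", paste0(material, ".txt"),
    package = "cxbeam", mustWork = TRUE
  )
  header <- readLines(path, n = 1L)
  density <- as.numeric(sub(".*density\\s+", "", header))
  raw <- read.table(path, comment.char = "#",
    col.names = c("energy_mev", "mu_over_rho", "mu_en_over_rho")
  )
  tab <- as_tibble(raw)
  stopifnot(
    all(diff(tab$energy_mev) > 0),
    all(tab$mu_over_rho > 0),
    all(tab$mu_en_over_rho > 0),
    all(tab$mu_en_over_rho <= tab$mu_over_rho)
  )
  attr(tab, "material") <- material
  attr(tab, "default_density") <- density
  the$materials[[material]] <- tab
  tab
}

#' @rdname material_table
#' @export
material_names <- function() {
  c("water", "bone", "lung", "air", "tungsten")
}

#' @rdname material_table
#' @export
material_density <- function(material) {
  attr(material_table(material), "default_density")
}

match_material <- function(material) {
  if (!is.character(material) || length(material) != 1L) {
    abort("`material` must be a single material label.")
  }
  # soft tissue is modelled as water
  if (material %in% c("soft", "tissue")) material <- "water"
  if (material %in% c("W", "w")) material <- "tungsten"
  if (!material %in% material_names()) {
    abort(paste0(
      "Unknown material '", material, "'. Known materials: ",
      paste(material_names(), collapse = ", "), "."
    ))
  }
  material
}

loglog_interp <- function(tab, energy_mev, column) {
  lo <- tab$energy_mev[1L]
  hi <- tab$energy_mev[nrow(tab)]
  if (any(energy_mev < lo | energy_mev > hi)) {
    abort(sprintf(
      "Photon energy outside the tabulated span [%g, %g] MeV for material '%s'.",
      lo, hi, attr(tab, "material")
    ))
  }
  out <- approx(
    x = log(tab$energy_mev), y = log(tab[[column]]),
    xout = log(energy_mev), method = "linear", ties = "ordered"
  )$y
  # exact table values at the knots (log/exp round-trip can wobble in the lsb)
  knot <- match(energy_mev, tab$energy_mev)
  hit <- !is.na(knot)
  out <- exp(out)
  out[hit] <- tab[[column]][knot[hit]]
  out
}

#' Mass attenuation and mass energy-absorption coefficients
#'
#' Log-log interpolation of the embedded material tables.  Both functions are
#' vectorised over `energy_mev`.
#'
#' @param material Material label, one of [material_names()] (the aliases
#'   `"soft"`/`"tissue"` map to water, `"W"` to tungsten).
#' @param energy_mev Photon energies in MeV, inside the tabulated span.
#' @return Coefficient values in cm^2/g.
#' @examples
#' mu_over_rho("water", 1.25)      # 0.0632 cm^2/g
#' mu_en_over_rho("water", 1.25)
#' @export
mu_over_rho <- function(material, energy_mev) {
  loglog_interp(material_table(material), energy_mev, "mu_over_rho")
}

#' @rdname mu_over_rho
#' @export
mu_en_over_rho <- function(material, energy_mev) {
  loglog_interp(material_table(material), energy_mev, "mu_en_over_rho")
}
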