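PHANTOM_LABELS <- c("air", "lung", "soft", "bone", "tungsten")

# soft tissue is water-equivalent; the rest map one-to-one
label_to_material <- c(
  air = "air", lung = "lung", soft = "water", bone = "bone",
  tungsten = "tungsten"
)

#' Default density map for phantom labels
#'
#' g/cm^3 per material label: air 0.0012, lung 0.26, soft 1.0, bone 1.85,
#' tungsten 19.3.
#' @export
default_densities <- function() {
  c(air = 0.0012, lung = 0.26, soft = 1.0, bone = 1.85, tungsten = 19.3)
}

#' Voxel phantom container
#'
#' A regular voxel grid with a material label and a density per voxel, plus
#' optional named boolean structure masks (PTV, organs at risk).  Voxel
#' indices are addressed `[ix, iy, iz]` with x fastest; `origin` is the
#' world coordinate of the centre of voxel (1,1,1) and +z is the optical
#' axis.
#'
#' @param labels 3D character (or factor) array of labels from
#'   `c("air","lung","soft","bone","tungsten")`, stored internally as
#'   integer codes.
#' @param spacing Voxel spacing, cm (scalar or per-axis).
#' @param origin Centre of the first voxel, cm.  Default centres the grid on
#'   the world origin.
#' @param densities Named density overrides, g/cm^3.
#' @param masks Named list of logical arrays congruent with `labels`.
#' @return An object of class `voxel_phantom` with elements `origin`,
#'   `spacing`, `dim`, `label` (integer array, levels attribute), `density`,
#'   `masks`.
#' @export
voxel_phantom <- function(labels, spacing, origin = NULL,
                          densities = default_densities(),
                          masks = list()) {
  spacing <- rep(spacing, length.out = 3)
  dm <- dim(labels)
  stopifnot(length(dm) == 3L)
  if (is.character(labels)) {
    code <- array(match(labels, PHANTOM_LABELS), dim = dm)
  } else {
    code <- labels
  }
  if (anyNA(code)) abort("Unknown phantom label; see `default_densities()` names.")
  dens <- default_densities()
  dens[names(densities)] <- densities
  if (any(dens[PHANTOM_LABELS != "air"] <= 0)) {
    abort("Densities must be positive.")
  }
  density <- array(dens[PHANTOM_LABELS][code], dim = dm)
  if (is.null(origin)) origin <- -(dm - 1) / 2 * spacing
  for (nm in names(masks)) {
    if (!identical(dim(masks[[nm]]), dm)) {
      abort(sprintf("Mask '%s' is not congruent with the phantom grid.", nm))
    }
  }
  structure(
    list(
      origin = origin, spacing = spacing, dim = dm,
      label = structure(code, levels = PHANTOM_LABELS),
      density = density, masks = masks
    ),
    class = "voxel_phantom"
  )
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat(sprintf(
    "<voxel_phantom> %d x %d x %d voxels, spacing %.3g cm; masks: %s\n",
    x$dim[1], x$dim[2], x$dim[3], x$spacing[1],
    if (length(x$masks)) paste(names(x$masks), collapse = ", ") else "none"
  ))
  tbl <- table(factor(PHANTOM_LABELS[x$label], levels = PHANTOM_LABELS))
  print(tbl[tbl > 0])
  invisible(x)
}

#' World coordinates of voxel centres along each axis
#' @param phantom A `voxel_phantom` (or `dose_grid`).
#' @return List with `x`, `y`, `z` coordinate vectors, cm.
#' @export
voxel_centers <- function(phantom) {
  list(
    x = phantom$origin[1] + (seq_len(phantom$dim[1]) - 1) * phantom$spacing[1],
    y = phantom$origin[2] + (seq_len(phantom$dim[2]) - 1) * phantom$spacing[2],
    z = phantom$origin[3] + (seq_len(phantom$dim[3]) - 1) * phantom$spacing[3]
  )
}

#' Segment a CT image into a voxel phantom by HU thresholding
#'
#' Three-way Hounsfield-unit thresholding into air, soft tissue and compact
#' bone (defaults: air below -800 HU, soft tissue -800 to +200, bone above
#' +200), with an optional lung mask that overrides the thresholds wherever
#' it is set — mirroring specialist-contoured lung segmentation, which
#' yields the four-region thorax model.  Densities are assigned per label.
#'
#' @param hu 3D numeric array of Hounsfield units.
#' @param thresholds `c(air_hi =, soft_hi =)`, strictly increasing.
#' @param lung_mask Optional logical array; voxels inside are labelled lung
#'   regardless of HU.
#' @inheritParams voxel_phantom
#' @return A [voxel_phantom()].
#' @export
segment_ct <- function(hu, thresholds = c(air_hi = -800, soft_hi = 200),
                       lung_mask = NULL, spacing = 0.2, origin = NULL,
                       densities = default_densities()) {
  if (thresholds[1] >= thresholds[2]) {
    abort("`thresholds` must be strictly increasing (air_hi < soft_hi).")
  }
  lab <- array("soft", dim = dim(hu))
  lab[hu < thresholds[1]] <- "air"
  lab[hu > thresholds[2]] <- "bone"
  if (!is.null(lung_mask)) {
    if (!identical(dim(lung_mask), dim(hu))) {
      abort("`lung_mask` is not congruent with the HU grid.")
    }
    lab[lung_mask] <- "lung"
  }
  voxel_phantom(lab, spacing = spacing, origin = origin,
    densities = densities)
}

#' Synthetic phantoms
#'
#' `make_water_cube()` builds the water-equivalent cube used for in-phantom
#' dosimetry; `make_head_phantom()` an ellipsoidal cranium (bone shell, soft
#' interior, spherical PTV, brainstem-like cylindrical organ at risk);
#' `make_thorax_phantom()` a soft-tissue body with two low-density lungs, a
#' bone spine, a spherical PTV inside one lung and a heart-like mask.  All
#' are deterministic functions of their parameters.
#'
#' @param side Cube side, cm.
#' @param spacing Voxel spacing, cm.
#' @return A [voxel_phantom()].
#' @export
make_water_cube <- function(side = 10, spacing = 0.2) {
  n <- as.integer(round(side / spacing))
  voxel_phantom(array("soft", dim = c(n, n, n)), spacing = spacing)
}

sphere_mask <- function(cc, center, radius) {
  outer(outer((cc$x - center[1])^2, (cc$y - center[2])^2, "+"),
    (cc$z - center[3])^2, "+") <= radius^2
}

#' @rdname make_water_cube
#' @param half_axes Outer skull half-axes `c(ax, ay, az)`, cm.
#' @param skull_thickness Bone shell thickness, cm.
#' @param ptv_center,ptv_radius Spherical planning target volume, cm.
#' @export
make_head_phantom <- function(spacing = 0.4, half_axes = c(8, 9.5, 7),
                              skull_thickness = 0.6,
                              ptv_center = c(2.5, 0, 1), ptv_radius = 1.2) {
  ext <- half_axes + 1
  dm <- as.integer(2 * ceiling(ext / spacing) + 1)
  lab <- array("air", dim = dm)
  ph0 <- voxel_phantom(lab, spacing = spacing)
  cc <- voxel_centers(ph0)
  rr <- function(scale) {
    outer(outer((cc$x / scale[1])^2, (cc$y / scale[2])^2, "+"),
      (cc$z / scale[3])^2, "+")
  }
  lab[rr(half_axes) <= 1] <- "bone"
  lab[rr(half_axes - skull_thickness) <= 1] <- "soft"
  ptv <- sphere_mask(cc, ptv_center, ptv_radius) & lab == "soft"
  stem <- outer(outer((cc$x + 1)^2, (cc$y - 2)^2, "+"),
    rep(0, length(cc$z)), "+") <= 1^2
  stem <- stem & rep(abs(cc$z) <= 4, each = dm[1] * dm[2]) & lab == "soft"
  voxel_phantom(lab, spacing = spacing,
    masks = list(ptv = ptv, brainstem = stem))
}

#' @rdname make_water_cube
#' @param body_half_axes Body ellipse half-axes `c(ax, ay)`, cm.
#' @param body_length z extent of the body, cm.
#' @param lung_half_axes Lung ellipsoid half-axes, cm.
#' @export
make_thorax_phantom <- function(spacing = 0.4, body_half_axes = c(15, 10),
                                body_length = 20,
                                lung_half_axes = c(5, 6.5, 8),
                                ptv_center = c(6, 0, 1), ptv_radius = 1.5) {
  dm <- as.integer(c(
    2 * ceiling((body_half_axes[1] + 1) / spacing) + 1,
    2 * ceiling((body_half_axes[2] + 1) / spacing) + 1,
    2 * ceiling((body_length / 2 + 1) / spacing) + 1
  ))
  lab <- array("air", dim = dm)
  ph0 <- voxel_phantom(lab, spacing = spacing)
  cc <- voxel_centers(ph0)
  body2 <- outer((cc$x / body_half_axes[1])^2, (cc$y / body_half_axes[2])^2, "+")
  inbody <- outer(body2 <= 1, abs(cc$z) <= body_length / 2, "&")
  lab[inbody] <- "soft"
  lung <- function(cx) {
    outer(outer(((cc$x - cx) / lung_half_axes[1])^2,
      (cc$y / lung_half_axes[2])^2, "+"),
      (cc$z / lung_half_axes[3])^2, "+") <= 1
  }
  lungs <- lung(-7) | lung(7)
  lab[lungs & inbody] <- "lung"
  spine <- outer(outer(cc$x^2, (cc$y + 7)^2, "+"),
    rep(0, length(cc$z)), "+") <= 1.5^2
  spine <- spine & inbody
  lab[spine] <- "bone"
  ptv <- sphere_mask(cc, ptv_center, ptv_radius) & lab == "lung"
  heart <- sphere_mask(cc, c(-1.5, 1.5, -2), 4) & lab == "soft"
  voxel_phantom(lab, spacing = spacing,
    masks = list(ptv = ptv, heart = heart))
}

#' Write / read a voxel phantom as an array container with a JSON sidecar
#'
#' The grid metadata (origin, spacing, dimensions, label levels, density
#' map) goes to `<path>.json`; label codes and densities go to `<path>.dat.gz`
#' as gzip-compressed text.
#'
#' @param phantom A [voxel_phantom()].
#' @param path Base path (without extension).
#' @return `read_phantom()` returns the phantom; `write_phantom()` the base
#'   path, invisibly.
#' @export
write_phantom <- function(phantom, path) {
  meta <- list(
    format = "cxbeam-phantom-1", origin = phantom$origin,
    spacing = phantom$spacing, dim = phantom$dim,
    labels = PHANTOM_LABELS, masks = names(phantom$masks)
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA)
  con <- gzfile(paste0(path, ".dat.gz"), "w")
  on.exit(close(con))
  writeLines(c(
    paste(as.integer(phantom$label), collapse = " "),
    paste(format(phantom$density, digits = 17), collapse = " "),
    vapply(phantom$masks, function(m) {
      paste(as.integer(m), collapse = " ")
    }, character(1))
  ), con)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "cxbeam-phantom-1")) {
    abort("Not a cxbeam phantom container.")
  }
  con <- gzfile(paste0(path, ".dat.gz"), "r")
  on.exit(close(con))
  lines <- readLines(con)
  dm <- as.integer(meta$dim)
  code <- array(as.integer(strsplit(lines[1], " ")[[1]]), dim = dm)
  masks <- list()
  if (length(meta$masks)) {
    for (i in seq_along(meta$masks)) {
      masks[[meta$masks[i]]] <-
        array(as.integer(strsplit(lines[2 + i], " ")[[1]]) == 1L, dim = dm)
    }
  }
  ph <- voxel_phantom(code, spacing = meta$spacing, origin = meta$origin,
    masks = masks)
  ph$density <- array(as.numeric(strsplit(lines[2], " ")[[1]]), dim = dm)
  ph
}

#' Patient-specific CT input (optional reader)
#'
#' Reading DICOM CT series and RT-STRUCT contours requires a DICOM reader
#' that this package does not bundle; the function is a guarded entry point
#' that directs users to supply pre-converted HU arrays to [segment_ct()]
#' when no reader is installed.
#'
#' @param dir Directory holding a DICOM CT series.
#' @export
read_ct_dicom <- function(dir) {
  if (!requireNamespace("oro.dicom", quietly = TRUE)) {
    abort(paste(
      "Reading DICOM requires the 'oro.dicom' package, which is not",
      "installed. Convert the series to an HU array (e.g. with any DICOM",
      "tool) and use segment_ct() directly."
    ))
  }
  ref <- oro.dicom::readDICOM(dir)
  abort("DICOM ingestion beyond HU arrays is not implemented; use segment_ct().")
}
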