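#' Simulation run configuration
#'
#' Bundles every stage of the chain — primary beam, target, collimator,
#' convergent geometry, phantom, turn integration and gantry arc — into one
#' validated configuration object.  All defaults reproduce the reference
#' device configuration: a 6.0 +/- 0.1 MeV electron beam, a 1.15 mm W
#' target, a 10 mm x 100 mm W collimator aimed from a ring of radius 10 cm
#' at 30 cm standoff onto the focus, 360 turn steps, no gantry rotation,
#' and a 10 cm water cube at 2 mm voxels centred on the focal spot.
#'
#' @param beam A [beam_spec()].
#' @param target A [target_spec()].
#' @param collimator A [collimator_spec()].
#' @param geometry A [convergent_geometry()] placing the target ring.
#' @param phantom Either a [voxel_phantom()] or a list
#'   `list(type = "water_cube"|"head"|"thorax", ...args)`.
#' @param turn_steps Angular steps of the 360-degree turn integration.
#' @param gantry `list(arc = c(start_deg, end_deg), step = deg)`; the arc is
#'   a rotation of the whole turn-integrated beam about the +x axis through
#'   the isocenter, sampled every `step` degrees inclusive of both ends.
#' @param gap_cm Target-to-collimator-entrance gap, cm.
#' @param exit_plane_z Phase-space scoring plane, cm.
#' @param seed Master seed; every stage derives its own stream from it.
#' @param chunk_size Primary histories per processing chunk.
#' @param n_batches History batches for the variance estimate.
#' @return A `run_config` object.
#' @export
run_config <- function(beam = beam_spec(), target = target_spec(),
                       collimator = collimator_spec(),
                       geometry = convergent_geometry(),
                       phantom = list(type = "water_cube", side = 10,
                         spacing = 0.2),
                       turn_steps = 360L,
                       gantry = list(arc = c(0, 0), step = 10),
                       gap_cm = 0.2, exit_plane_z = -21, seed = 1L,
                       chunk_size = 250000L, n_batches = 20L) {
  stopifnot(
    inherits(beam, "beam_spec"), inherits(target, "target_spec"),
    inherits(collimator, "collimator_spec"),
    inherits(geometry, "convergent_geometry"),
    turn_steps >= 1, gap_cm >= 0
  )
  arc <- gantry$arc %||% c(0, 0)
  if (any(arc < 0) || any(arc > 360) || arc[2] < arc[1]) {
    abort("Gantry `arc` must be an increasing interval within [0, 360].")
  }
  structure(
    list(
      beam = beam, target = target, collimator = collimator,
      geometry = geometry, phantom = phantom,
      turn_steps = as.integer(turn_steps), gantry = gantry,
      gap_cm = gap_cm, exit_plane_z = exit_plane_z, seed = as.integer(seed),
      chunk_size = as.integer(chunk_size), n_batches = as.integer(n_batches)
    ),
    class = "run_config"
  )
}

resolve_phantom <- function(phantom) {
  if (inherits(phantom, "voxel_phantom")) {
    return(phantom)
  }
  type <- phantom$type %||% abort("Phantom config needs a `type`.")
  args <- phantom[setdiff(names(phantom), "type")]
  switch(type,
    water_cube = do.call(make_water_cube, args),
    head = do.call(make_head_phantom, args),
    thorax = do.call(make_thorax_phantom, args),
    abort(sprintf("Unknown phantom type '%s'.", type))
  )
}

# map sampled electrons onto the target plane under ideal magnetic guidance:
# the transverse spot and the energy are preserved, the propagation direction
# is aligned with the bore axis (the tuned magnets centre the beam on the
# target; see the methods vignette for what this idealisation drops)
guide_to_target <- function(primaries, frame) {
  n <- nrow(primaries)
  tibble(
    x = frame$source[1] + primaries$x * frame$t1[1] + primaries$y * frame$t2[1],
    y = frame$source[2] + primaries$x * frame$t1[2] + primaries$y * frame$t2[2],
    z = frame$source[3] + primaries$x * frame$t1[3] + primaries$y * frame$t2[3],
    u = rep(frame$axis[1], n), v = rep(frame$axis[2], n),
    w = rep(frame$axis[3], n),
    energy_mev = primaries$energy_mev
  )
}

#' Run the full simulation chain
#'
#' Beam sampling, guidance onto the target ring, bremsstrahlung emission and
#' collimation, 360-degree turn integration, optional gantry arc, and
#' collision-kerma dose deposition — streamed in chunks so that arbitrarily
#' large turn-integrated phase spaces never have to be materialised.
#' Deterministic for a fixed configuration (including its seed).
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return A `cx_run` list: `config`, `config_hash`, `dose` (a `dose_grid`),
#'   `metrics` (tibble), `stage_log` (tibble of per-stage particle counts),
#'   and `static_records` (a capped sample of the static phase space for
#'   diagnostics).
#' @export
run_simulation <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  phantom <- resolve_phantom(config$phantom)
  frame <- device_frame(config$geometry, config$gap_cm, config$collimator)
  acc <- new_kerma_accumulator(phantom, config$n_batches)
  n_tot <- config$beam$n_histories
  seed <- config$seed
  g_arc <- config$gantry$arc %||% c(0, 0)
  g_step <- config$gantry$step %||% 10
  g_angles <- if (g_arc[2] > g_arc[1]) {
    a <- seq(g_arc[1], g_arc[2], by = g_step)
    # a full circle would double-count the shared endpoint
    if (g_arc[2] - g_arc[1] >= 360) a <- a[a < g_arc[1] + 360] else a
    a[a <= g_arc[2]]
  } else {
    g_arc[1]
  }
  turn <- config$turn_steps
  turn_angles <- 2 * pi * (seq_len(turn) - 1L) / turn
  n_chunks <- as.integer(ceiling(n_tot / config$chunk_size))
  counts <- c(primaries = 0, on_target = 0, accepted_static = 0,
    rays_transported = 0)
  keep <- NULL
  static_idx0 <- 0
  for (ci in seq_len(n_chunks)) {
    m <- min(config$chunk_size, n_tot - (ci - 1L) * config$chunk_size)
    prim <- sample_primaries(config$beam, m,
      seed = derive_seed(seed, "beam", ci))
    hits <- guide_to_target(prim, frame)
    counts[["primaries"]] <- counts[["primaries"]] + m
    counts[["on_target"]] <- counts[["on_target"]] + m
    rec <- emit_phase_space(
      hits, config$target, config$collimator, config$geometry,
      exit_plane_z = config$exit_plane_z,
      seed = derive_seed(seed, "emit", ci)
    )
    ns <- nrow(rec)
    counts[["accepted_static"]] <- counts[["accepted_static"]] + ns
    if (is.null(keep)) keep <- head(rec, 20000L)
    if (ns == 0L) next
    mm <- mu_matrices(acc, rec$energy_mev)
    pos0 <- cbind(rec$x, rec$y, rec$z)
    dir0 <- cbind(rec$u, rec$v, rec$w)
    mu_row <- seq_len(ns) - 1L
    batch <- (static_idx0 + seq_len(ns) - 1L) %% config$n_batches
    static_idx0 <- static_idx0 + ns
    block <- max(1L, as.integer(floor(2e6 / ns)))
    for (ga in g_angles) {
      gr <- ga * pi / 180
      cg <- cos(gr)
      sg <- sin(gr)
      k0 <- 1L
      while (k0 <= turn) {
        ks <- k0:min(turn, k0 + block - 1L)
        nb <- length(ks)
        ca <- rep(cos(turn_angles[ks]), each = ns)
        sa <- rep(sin(turn_angles[ks]), each = ns)
        px <- rep(pos0[, 1], nb); py <- rep(pos0[, 2], nb)
        pz <- rep(pos0[, 3], nb)
        ux <- rep(dir0[, 1], nb); uy <- rep(dir0[, 2], nb)
        uz <- rep(dir0[, 3], nb)
        # turn rotation about +z
        rx <- ca * px - sa * py; ry <- sa * px + ca * py
        ru <- ca * ux - sa * uy; rv <- sa * ux + ca * uy
        # gantry rotation about +x
        if (gr != 0) {
          y2 <- cg * ry - sg * pz; z2 <- sg * ry + cg * pz
          v2 <- cg * rv - sg * uz; w2 <- sg * rv + cg * uz
          ry <- y2; pz <- z2; rv <- v2; uz <- w2
        }
        accumulate_kerma(
          acc,
          pos = cbind(rx, ry, pz), dir = cbind(ru, rv, uz),
          energy_mev = rep(rec$energy_mev, nb),
          mu_row = rep(mu_row, nb), batch = rep(batch, nb),
          mu = mm$mu, muen = mm$muen
        )
        counts[["rays_transported"]] <- counts[["rays_transported"]] + ns * nb
        k0 <- k0 + block
      }
    }
    if (!quiet) {
      message(sprintf(
        "chunk %d/%d: %d primaries -> %d static records", ci, n_chunks, m, ns
      ))
    }
  }
  n_hist <- n_tot * turn * length(g_angles)
  dose <- finalize_dose(acc, n_hist)
  metrics <- run_metrics(dose)
  stage_log <- tibble(
    stage = c(
      "(1) primary electrons", "(5-7) guided onto target",
      "(8) collimator-accepted static records",
      "(9) turn/arc rays transported", "rays missing the phantom"
    ),
    count = c(counts, unname(dose$tallies["skipped"]))
  )
  structure(
    list(
      config = config, config_hash = rlang::hash(config), dose = dose,
      metrics = metrics, stage_log = stage_log, static_records = keep
    ),
    class = "cx_run"
  )
}

run_metrics <- function(dose) {
  ext95 <- tryCatch(mean_extension_95(dose), error = function(e) NA_real_)
  iso <- function(l) isodose_volume(dose, l)$volume_cm3
  tibble(
    metric = c(
      "dose_focal_sphere_gy_per_hist", "max_dose_gy_per_hist",
      "mean_extension_95_mm", "isodose_90_cm3", "isodose_75_cm3",
      "isodose_50_cm3", "isodose_25_cm3", "isodose_10_cm3",
      "energy_entered_mev", "energy_escaped_mev", "energy_scatter_mev"
    ),
    value = c(
      tryCatch(dose_in_focal_sphere(dose), error = function(e) NA_real_),
      max(dose$dose), ext95,
      iso(90), iso(75), iso(50), iso(25), iso(10),
      unname(dose$tallies["entered"]), unname(dose$tallies["escaped"]),
      unname(dose$tallies["scatter"])
    )
  )
}

#' @export
print.cx_run <- function(x, ...) {
  cat(sprintf("<cx_run> %s\n", x$config_hash))
  print(x$stage_log)
  print(x$metrics)
  invisible(x)
}

#' Write or read a run configuration as JSON
#'
#' `config_init()` writes the default configuration (all defaults spelled
#' out) to a JSON file; `read_run_config()` loads one, reporting unknown or
#' missing keys by name.
#'
#' @param path JSON file path.
#' @param config Configuration to serialise (default [run_config()]).
#' @return `read_run_config()` returns a `run_config`.
#' @export
config_init <- function(path, config = run_config()) {
  ser <- list(
    beam = unclass(config$beam),
    target = unclass(config$target),
    collimator = unclass(config$collimator),
    geometry = unclass(config$geometry)[c("L", "h", "focal_depth", "r0",
      "focal_spot")],
    phantom = config$phantom,
    turn_steps = config$turn_steps, gantry = config$gantry,
    gap_cm = config$gap_cm, exit_plane_z = config$exit_plane_z,
    seed = config$seed, chunk_size = config$chunk_size,
    n_batches = config$n_batches
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}

#' @rdname config_init
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("beam", "target", "collimator", "geometry")
  missing_keys <- setdiff(need, names(raw))
  if (length(missing_keys)) {
    abort(paste0("Config is missing key(s): ",
      paste(missing_keys, collapse = ", ")))
  }
  if (!is.null(raw$phantom)) raw$phantom <- as.list(raw$phantom)
  run_config(
    beam = do.call(beam_spec, raw$beam),
    target = do.call(target_spec, raw$target),
    collimator = do.call(collimator_spec, raw$collimator),
    geometry = do.call(convergent_geometry, raw$geometry),
    phantom = raw$phantom %||% list(type = "water_cube", side = 10,
      spacing = 0.2),
    turn_steps = raw$turn_steps %||% 360L,
    gantry = as.list(raw$gantry %||% list(arc = c(0, 0), step = 10)),
    gap_cm = raw$gap_cm %||% 0.2,
    exit_plane_z = raw$exit_plane_z %||% -21,
    seed = raw$seed %||% 1L,
    chunk_size = raw$chunk_size %||% 250000L,
    n_batches = raw$n_batches %||% 20L
  )
}
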