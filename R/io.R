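# Output plumbing: legacy-ASCII structured-points VTK export of lattice
# fields, YAML run configuration, and the standard run output set
# (counts.csv, events.csv, metrics.json, run manifest).

#' Write lattice fields to a legacy VTK structured-points file
#'
#' @param fields Named list of numeric arrays, all with the grid's
#'   dimensions (2D arrays are written as one-slice 3D).
#' @param grid The `lattice_grid`.
#' @param path Output file path (.vtk).
#' @param title Dataset title; physical units belong here.
#' @return Invisibly, `path`.
#' @export
write_vtk <- function(fields, grid, path, title = "thrombosim fields") {
  stopifnot(is.list(fields), length(fields) > 0)
  dims <- grid$dims
  d3 <- if (grid$dim == 2L) c(dims, 1L) else dims
  n <- prod(d3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d3[1], d3[2], d3[3]),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g %g", grid$spacing, grid$spacing,
                       grid$spacing),
               sprintf("POINT_DATA %d", n)), con)
  for (nm in names(fields)) {
    v <- as.numeric(fields[[nm]])
    stopifnot(length(v) == n)
    writeLines(c(sprintf("SCALARS %s double 1", gsub("[^A-Za-z0-9_]", "_", nm)),
                 "LOOKUP_TABLE default"), con)
    writeLines(formatC(v, format = "g", digits = 7), con)
  }
  invisible(path)
}

#' Export a grid (node flags) to VTK
#'
#' @param grid A `lattice_grid`.
#' @param path Output file path.
#' @export
write_vtk_grid <- function(grid, path) {
  write_vtk(list(flags = array(as.numeric(grid$flags), grid$dims)), grid,
            path, title = sprintf("lattice grid (%s, spacing um)",
                                  grid$spec$shape))
}

#' Read a simulation configuration from a YAML file
#'
#' Expected sections: `geometry` (shape, length_mm, inlet_diameter_mm,
#' area_reduction, constriction_length_mm, patch_length_mm,
#' circumference_fraction, spacing_um, dim), `flow` (inlet_wall_shear_s1,
#' plus optional [lb_control()] fields), `run` (scenario, duration_s, seed),
#' and optional `transport` / `lkmc` / `scenario_pars` parameter blocks.
#'
#' @param path YAML file path.
#' @param donor A `donor_model` to attach.
#' @return A [simulation_config()].
#' @export
read_sim_config <- function(path, donor) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read config files", call. = FALSE)
  y <- yaml::read_yaml(path)
  g <- y$geometry
  spec <- domain_spec(shape = g$shape,
                      length_mm = g$length_mm %||% 0.5,
                      inlet_diameter_mm = g$inlet_diameter_mm %||% 0.12,
                      area_reduction = g$area_reduction %||% 0.75,
                      constriction_length_mm = g$constriction_length_mm %||% 0.5,
                      patch_length_mm = g$patch_length_mm %||%
                        (if (g$shape == "stenosis") g$constriction_length_mm %||% 0.5 else 0.25),
                      circumference_fraction = g$circumference_fraction %||% 0.5,
                      spacing_um = g$spacing_um %||% 3,
                      dim = g$dim %||% 2)
  lbargs <- y$flow[setdiff(names(y$flow), "inlet_wall_shear_s1")]
  simulation_config(
    spec = spec,
    inlet_wall_shear = y$flow$inlet_wall_shear_s1,
    donor = donor,
    scenario = y$run$scenario %||% "control",
    duration = y$run$duration_s %||% 360,
    seed = y$run$seed %||% 1L,
    lb = do.call(lb_control, lbargs %||% list()),
    transport = do.call(transport_params, y$transport %||% list()),
    lkmc = do.call(lkmc_params, y$lkmc %||% list()),
    scenario_pars = do.call(scenario_params, y$scenario_pars %||% list()))
}

#' Write the standard output set of a run
#'
#' Writes `counts.csv` (time, N), `events.csv`, `metrics.json` and
#' `manifest.json` (scenario, seed, geometry and parameter echo) into a
#' directory.
#'
#' @param traj A `trajectory`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_run_outputs <- function(traj, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(traj$counts, file.path(dir, "counts.csv"),
                   row.names = FALSE)
  utils::write.csv(traj$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  met <- compute_metrics(traj)
  jsonlite::write_json(unclass(met), file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  cfg <- traj$config
  manifest <- list(scenario = cfg$scenario, seed = cfg$seed,
                   duration_s = cfg$duration,
                   inlet_wall_shear_s1 = cfg$inlet_wall_shear,
                   geometry = unclass(cfg$spec),
                   lkmc = unclass(cfg$lkmc),
                   transport = unclass(cfg$transport),
                   hill = unclass(cfg$hill),
                   donor = cfg$donor$provenance)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(traj$conc)) {
    write_vtk(list(ADP_uM = traj$conc$species$ADP,
                   TXA2_uM = traj$conc$species$TXA2),
              traj$grid, file.path(dir, "concentrations.vtk"),
              title = "agonist concentrations (uM)")
  }
  invisible(dir)
}
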