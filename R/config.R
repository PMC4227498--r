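## Run configuration (YAML), presets, and the command entry points used
## by the `headfem` script: mesh generation + quality audit, simulation
## with provenance logging, and offline metrics re-analysis.

default_run_config <- function() {
  list(
    geometry = list(brain_semiaxes = c(0.085, 0.065, 0.060),
                    csf_thickness = 0.003, skull_thickness = 0.007,
                    scalp_thickness = 0, edge_length = 0.008,
                    skull_layers = 1, include_brainstem = FALSE,
                    foramen_magnum = FALSE, fm_radius = 0.008,
                    jitter = 0, seed = 1),
    materials = list(units = "mixed", target_mass = 4.5,
                     cavity_bulk = 2.19e9, csf_shear = 1e3,
                     csf_bulk = 2.19e7),
    solver = list(safety = 0.8, duration = 0.006, output_interval = 5e-5,
                  vol_average = TRUE, corotational = FALSE, use_cavity = TRUE,
                  seed = 1),
    loadcase = list(name = "nahum_case37", mode = "pulse", peak = 7400,
                    pulse_duration = 0.006, angle_deg = 45,
                    site = "frontal", velocity = 5),
    metrics = list(hic_window = 0.036, compression = 234e3, tension = -186e3,
                   hic_limit = 1000))
}

#' Load a run configuration from YAML
#'
#' Missing fields fall back to the packaged defaults; all quantities are
#' SI. Basic schema validation names the offending field.
#'
#' @param path YAML file, or `NULL` for the defaults.
#' @param preset optional preset name (see [preset_config()]); applied
#'   before the file overrides.
#' @return nested configuration list of class `run_config`.
#' @export
read_run_config <- function(path = NULL, preset = NULL) {
  cfg <- default_run_config()
  if (!is.null(preset)) {
    cfg <- modifyList(cfg, preset_config(preset))
    attr(cfg, "preset") <- preset
  }
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.list(user)) stop("config must be a YAML mapping")
    extra <- setdiff(names(user), names(cfg))
    if (length(extra)) stop("unknown config section: ", extra[1])
    cfg <- modifyList(cfg, user)
  }
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  g <- cfg$geometry
  chk <- function(ok, field) if (!ok) stop("invalid config field: ", field)
  chk(length(g$brain_semiaxes) == 3 && all(g$brain_semiaxes > 0),
      "geometry.brain_semiaxes")
  chk(is.numeric(g$csf_thickness) && g$csf_thickness > 0,
      "geometry.csf_thickness")
  chk(is.numeric(g$skull_thickness) && g$skull_thickness > 0,
      "geometry.skull_thickness")
  chk(is.numeric(g$edge_length) && g$edge_length > 0, "geometry.edge_length")
  chk(cfg$solver$safety > 0 && cfg$solver$safety <= 1, "solver.safety")
  chk(cfg$solver$duration > 0, "solver.duration")
  chk(cfg$materials$target_mass > 0, "materials.target_mass")
  chk(cfg$metrics$compression > 0 && cfg$metrics$tension < 0,
      "metrics.compression/tension")
  invisible(cfg)
}

#' Packaged run presets
#'
#' `nahum37-coarse` (8 mm edge) and `nahum37-fine` (5 mm edge) frontal
#' force-pulse replications, `anvil-occipital` (hemispherical anvil) and
#' `hardy-ndt` (frontal pulse with NDT columns and a 40 ms window).
#'
#' @param name preset name.
#' @return configuration override list.
#' @export
preset_config <- function(name = c("nahum37-coarse", "nahum37-fine",
                                   "anvil-occipital", "hardy-ndt")) {
  name <- match.arg(name)
  switch(name,
    "nahum37-coarse" = list(geometry = list(edge_length = 0.008)),
    "nahum37-fine" = list(geometry = list(edge_length = 0.005)),
    "anvil-occipital" = list(
      geometry = list(edge_length = 0.008),
      loadcase = list(name = "anvil", site = "occipital", velocity = 5,
                      mode = "impactor"),
      solver = list(duration = 0.004)),
    "hardy-ndt" = list(
      geometry = list(edge_length = 0.008),
      solver = list(duration = 0.012),
      loadcase = list(peak = 3000, pulse_duration = 0.006)))
}

config_mesh <- function(cfg) {
  g <- cfg$geometry
  build_head_mesh(head_config(
    brain_semiaxes = g$brain_semiaxes, csf_thickness = g$csf_thickness,
    skull_thickness = g$skull_thickness, scalp_thickness = g$scalp_thickness,
    edge_length = g$edge_length, skull_layers = g$skull_layers,
    include_brainstem = g$include_brainstem,
    foramen_magnum = g$foramen_magnum, fm_radius = g$fm_radius,
    jitter = g$jitter, seed = g$seed))
}

config_loadcase <- function(cfg, mesh) {
  lc <- cfg$loadcase
  if (identical(lc$name, "anvil"))
    anvil_case(mesh, site = lc$site, velocity = lc$velocity)
  else if (identical(lc$name, "null"))
    null_loadcase(mesh)
  else
    nahum_case37(mesh, peak = lc$peak, duration = lc$pulse_duration,
                 angle_deg = lc$angle_deg, mode = lc$mode)
}

#' Generate a mesh and its quality report from a configuration
#'
#' Writes `mesh.vtk`, `mesh.msh` and `quality.json` into `out_dir`.
#'
#' @param config path to a YAML config, a `run_config`, or `NULL` for
#'   defaults.
#' @param out_dir output directory (created if absent).
#' @param preset optional preset name.
#' @return the `head_mesh`, invisibly.
#' @export
cmd_mesh <- function(config = NULL, out_dir = ".", preset = NULL) {
  cfg <- if (inherits(config, "run_config")) config
         else read_run_config(config, preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mesh <- config_mesh(cfg)
  write_mesh_vtk(mesh, file.path(out_dir, "mesh.vtk"))
  write_mesh_msh(mesh, file.path(out_dir, "mesh.msh"))
  q <- quality_report(mesh)
  jsonlite::write_json(
    list(n_nodes = nrow(mesh$nodes), n_elements = nrow(mesh$elems),
         aspect_ratio_mean = mean(q$aspect_ratio),
         aspect_ratio_max = max(q$aspect_ratio),
         min_dihedral_deg = min(q$min_dihedral),
         edge_mean_m = q$edge_mean, edge_min_m = q$edge_min,
         edge_max_m = q$edge_max,
         n_flagged_aspect = q$n_flagged_aspect,
         n_flagged_dihedral = q$n_flagged_dihedral),
    file.path(out_dir, "quality.json"), auto_unbox = TRUE, digits = NA)
  invisible(mesh)
}

#' Run a simulation from a configuration
#'
#' Writes `history.csv`, `injury_report.json`, a `provenance.json` log
#' (unit interpretation, dt, element count, energy balance, seed) and a
#' final-state von Mises field `von_mises.vtk` into `out_dir`.
#'
#' @inheritParams cmd_mesh
#' @param mesh optional pre-built `head_mesh` (built from the config when
#'   `NULL`).
#' @return the `impact_history`, invisibly.
#' @export
cmd_simulate <- function(config = NULL, out_dir = ".", preset = NULL,
                         mesh = NULL) {
  cfg <- if (inherits(config, "run_config")) config
         else read_run_config(config, preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$solver$seed)
  if (is.null(mesh)) mesh <- config_mesh(cfg)
  registry <- material_registry(units = cfg$materials$units)
  lc <- config_loadcase(cfg, mesh)
  probes <- place_pressure_probes(mesh)
  ndt <- if (identical(attr(cfg, "preset"), "hardy-ndt") ||
             isTRUE(cfg$loadcase$ndt)) place_ndt_columns(mesh) else NULL
  hist <- simulate_impact(
    mesh, lc, registry, duration = cfg$solver$duration,
    safety = cfg$solver$safety, output_interval = cfg$solver$output_interval,
    target_mass = cfg$materials$target_mass, probes = probes, ndt = ndt,
    use_cavity = cfg$solver$use_cavity, cavity_bulk = cfg$materials$cavity_bulk,
    csf_shear = cfg$materials$csf_shear, csf_bulk = cfg$materials$csf_bulk,
    vol_average = cfg$solver$vol_average,
    corotational = cfg$solver$corotational)
  write_history_csv(hist, file.path(out_dir, "history.csv"))
  thr <- tolerance_thresholds(cfg$metrics$compression, cfg$metrics$tension,
                              cfg$metrics$hic_limit)
  rep <- injury_report(hist, thr, hic_window = cfg$metrics$hic_window)
  write_injury_report(rep, file.path(out_dir, "injury_report.json"))
  jsonlite::write_json(
    list(unit_interpretation = hist$settings$unit_interpretation,
         cavity_bulk_Pa = hist$settings$cavity_bulk,
         csf_shear_Pa = hist$settings$csf_shear,
         csf_bulk_Pa = hist$settings$csf_bulk,
         dt_s = hist$dt, n_steps = hist$nsteps,
         n_elements = nrow(mesh$elems), n_nodes = nrow(mesh$nodes),
         total_mass_kg = hist$total_mass, density_scale = hist$density_scale,
         energy_balance_error = max(abs(hist$channels$balance_error)),
         seed = cfg$solver$seed),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  vm <- von_mises(hist$final_stress)
  write_field_vtk(mesh, vm, "von_mises", file.path(out_dir, "von_mises.vtk"))
  invisible(hist)
}

#' Recompute injury metrics offline from a stored history
#'
#' @param history_path a `history.csv` written by [cmd_simulate()].
#' @param out_path optional JSON output path.
#' @param thresholds a [tolerance_thresholds()].
#' @param hic_window HIC window cap (s).
#' @return the `injury_report`.
#' @export
cmd_metrics <- function(history_path, out_path = NULL,
                        thresholds = tolerance_thresholds(),
                        hic_window = 0.036) {
  ch <- read_history_csv(history_path)
  need <- c("time", "acc_mag", "impact_force")
  miss <- setdiff(need, names(ch))
  if (length(miss)) stop("history is missing channel(s): ",
                         paste(miss, collapse = ", "))
  fake <- structure(list(channels = ch, loadcase = list(pulse = NULL),
                         peaks = list(brain_von_mises = NA_real_,
                                      brain_von_mises_time = NA_real_,
                                      brain_von_mises_elem = NA_integer_,
                                      skull_principal = NA_real_,
                                      skull_principal_time = NA_real_,
                                      skull_principal_elem = NA_integer_)),
                    class = "impact_history")
  rep <- injury_report(fake, thresholds, hic_window)
  if (!is.null(out_path)) write_injury_report(rep, out_path)
  rep
}
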