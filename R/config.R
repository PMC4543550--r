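#' Default scenario configuration
#'
#' Returns the full parameter set of the model with its standard values:
#' crypt geometry (160 um tall, 60 um wide test tube, 10 um cells of
#' N = 20 elements), mechanical potentials (intra-cell spring mu = 2.5,
#' r0 = 1.5 um; inter-cell Lennard-Jones eps = 0.05, sigma = 4.5 um,
#' cutoff 10 um; wall adhesion eps_external = 0.001, cutoff 5 um; vertical
#' drag b_z = -0.3), time steps (3.6 s mechanics, 0.0036 s chemistry,
#' 1000 substeps), signaling thresholds (TH_Wnt = 0.85, TH_BMP = 0.15,
#' TH_Notch = 0.3), Notch ligand weights (0.35 Paneth, 1.0 Goblet),
#' Wnt field constants (D_c = 10 um^2/s, d_c = 1e-3 /s, per-element
#' secretion delta_c = 0.01), cycle and Paneth-lifetime distributions,
#' and the experiment switches used by the scenario definitions.
#'
#' @return A named list of class \code{scenario_config}.
#' @export
default_config <- function() {
  cfg <- list(
    # geometry
    cell_diameter = 10,
    crypt_height = 160,
    crypt_diameter = 60,
    elements_per_cell = 20L,
    # mechanics
    mu = 2.5,
    r0 = 1.5,
    eps_lj = 0.05,
    sigma_lj = 4.5,
    lj_cutoff = 10.0,
    eps_external = 0.001,
    wall_cutoff = 5.0,
    b_z = -0.3,
    mobility = 60,               # um/h of velocity per unit potential force
    max_step_um = 0.5,           # per-step displacement clamp, um
    paneth_bias_speed = 2.0,     # um/h downhill migration of Paneth cells
    # time stepping
    dt_mech = 3.6,               # s
    dt_chem = 0.0036,            # s
    chem_substeps = 1000L,
    # signaling thresholds and weights
    th_wnt = 0.85,
    th_bmp = 0.15,
    th_notch = 0.3,
    np_paneth = 0.35,
    np_goblet = 1.0,
    contact_distance = 6.0,      # um between elements of touching cells
                                 # (just beyond the inter-cell equilibrium
                                 # separation 2^(1/6) sigma ~ 5.05 um)
    # diffusible Wnt field
    delta_c = 0.01,
    D_c = 10,                    # um^2/s (= 1e-7 cm^2/s)
    d_c = 1e-3,                  # /s
    grid_spacing = 1.0,          # um
    grid_margin = 5.0,           # um of padding around the crypt box
    chem_mode = "explicit",      # or "quasi_steady"
    rho_sat = NA_real_,          # el/um^3; NA = 3N / sphere(cell_diameter)
    # lifecycle distributions
    cycle_mean_h = 24,
    cycle_sd_h = 4,
    cycle_bounds_h = c(20, 28),
    paneth_life_mean_wk = 8,
    paneth_life_sd_wk = 2,
    paneth_life_bounds_wk = c(6, 10),
    # experiment switches
    wnt_production_pct = 100,
    global_wnt_on = TRUE,
    bmp_on = TRUE,
    paneth_migration_on = TRUE,
    noise_sigma_wnt = 0,
    noise_sigma_bmp = 0,
    drag_multiplier = 1,
    cycle_shift_h = 0,
    allow_stem_reentry = FALSE,
    # engine cadences and construction knobs
    lifecycle_every = 1L,        # mechanical steps per lifecycle update
    chem_refresh_every = 1L,     # mechanical steps per chemistry update
    packing_cycle_h = 0.5,       # division interval of the packing phase
    pack_crowd_max = 4L,         # packing: divide only with <= this many
                                 # contacting neighbors (confluence gate)
    stability_slope = 0.1,       # cd/h trailing slope flagged unstable
    stability_occupancy = 0.9,   # fraction of total arc flagged unstable
    seed = 1L
  )
  class(cfg) <- "scenario_config"
  cfg
}

# fields that must be strictly positive
.positive_fields <- c(
  "cell_diameter", "crypt_height", "crypt_diameter", "elements_per_cell",
  "mu", "r0", "eps_lj", "sigma_lj", "lj_cutoff", "eps_external",
  "wall_cutoff", "dt_mech", "dt_chem", "chem_substeps", "th_wnt", "th_bmp",
  "th_notch", "np_paneth", "np_goblet", "contact_distance", "delta_c",
  "D_c", "d_c", "grid_spacing", "grid_margin", "cycle_mean_h", "cycle_sd_h",
  "paneth_life_mean_wk", "paneth_life_sd_wk", "drag_multiplier",
  "mobility", "max_step_um",
  "lifecycle_every", "chem_refresh_every", "packing_cycle_h",
  "stability_slope", "stability_occupancy"
)

#' Validate a scenario configuration
#'
#' Checks positivity constraints, the sign of the drag coefficient, the
#' consistency dt_mech = chem_substeps * dt_chem, the explicit-diffusion
#' stability bound D_c * dt_chem / grid_spacing^2 <= 1/6, and that the
#' truncation bounds bracket their means.
#'
#' @param config a \code{scenario_config}.
#' @return The config, invisibly; errors name the offending field.
#' @export
validate_config <- function(config) {
  for (f in .positive_fields) {
    if (!all(is.finite(config[[f]])) || any(config[[f]] <= 0))
      stop("validation error: field '", f, "' must be strictly positive")
  }
  if (!is.finite(config$b_z) || config$b_z >= 0)
    stop("validation error: field 'b_z' must be negative")
  for (f in c("noise_sigma_wnt", "noise_sigma_bmp", "wnt_production_pct",
              "paneth_bias_speed")) {
    if (!is.finite(config[[f]]) || config[[f]] < 0)
      stop("validation error: field '", f, "' must be >= 0")
  }
  if (abs(config$dt_mech - config$chem_substeps * config$dt_chem) >
      1e-9 * config$dt_mech)
    stop("validation error: field 'dt_mech' must equal chem_substeps * dt_chem")
  ratio <- config$D_c * config$dt_chem / config$grid_spacing^2
  if (ratio > 1 / 6 + 1e-12)
    stop("validation error: field 'dt_chem' violates the explicit stability ",
         "bound D_c*dt_chem/grid_spacing^2 <= 1/6 (got ", signif(ratio, 4), ")")
  if (!(config$cycle_bounds_h[1] < config$cycle_mean_h &&
        config$cycle_mean_h < config$cycle_bounds_h[2]))
    stop("validation error: field 'cycle_bounds_h' must bracket cycle_mean_h")
  if (!(config$paneth_life_bounds_wk[1] < config$paneth_life_mean_wk &&
        config$paneth_life_mean_wk < config$paneth_life_bounds_wk[2]))
    stop("validation error: field 'paneth_life_bounds_wk' must bracket ",
         "paneth_life_mean_wk")
  if (!config$chem_mode %in% c("explicit", "quasi_steady"))
    stop("validation error: field 'chem_mode' must be 'explicit' or ",
         "'quasi_steady'")
  invisible(config)
}

#' Load a scenario configuration
#'
#' Overlays a flat key-value document (a YAML file path or a named list)
#' onto the defaults of \code{\link{default_config}} and validates the
#' result. Unknown keys are rejected.
#'
#' @param source \code{NULL} (defaults), a path to a YAML file, or a named
#'   list of overrides.
#' @return A validated \code{scenario_config}.
#' @export
load_config <- function(source = NULL) {
  cfg <- default_config()
  if (is.null(source)) {
    validate_config(cfg)
    return(cfg)
  }
  if (is.character(source) && length(source) == 1) {
    overrides <- yaml::read_yaml(source)
  } else if (is.list(source)) {
    overrides <- source
  } else {
    stop("configuration error: source must be a path or a named list")
  }
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown))
      stop("configuration error: unknown key(s): ",
           paste(unknown, collapse = ", "))
    for (k in names(overrides)) {
      v <- overrides[[k]]
      if (is.integer(cfg[[k]]) && is.numeric(v)) v <- as.integer(v)
      if (is.list(v)) v <- unlist(v)
      cfg[[k]] <- v
    }
  }
  validate_config(cfg)
  cfg
}

#' Write a configuration to a YAML file
#'
#' @param config a \code{scenario_config}.
#' @param path output file path.
#' @return \code{path}, invisibly. \code{load_config(write_config(x)) == x}.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @export
#' @method print scenario_config
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  crypt %g x %g um, cells %g um (%d elements)\n",
              x$crypt_diameter, x$crypt_height, x$cell_diameter,
              x$elements_per_cell))
  cat(sprintf("  local Wnt %g%%, global Wnt %s, BMP %s, Paneth migration %s\n",
              x$wnt_production_pct, x$global_wnt_on, x$bmp_on,
              x$paneth_migration_on))
  cat(sprintf("  chem_mode %s, grid %g um, noise (wnt %g, bmp %g)\n",
              x$chem_mode, x$grid_spacing, x$noise_sigma_wnt,
              x$noise_sigma_bmp))
  invisible(x)
}

# format a numeric column at full (round-trip) precision
.fmt_full <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}

#' Write a per-time summary series to delimited text
#'
#' Columns: \code{time_h, n_stem, n_paneth, n_enterocyte, n_goblet,
#' niche_height_cd}. Values are written at full precision so a read-back
#' reproduces them bit-exactly.
#'
#' @param records data frame of time-ordered records with those columns.
#' @param sink output path.
#' @return Number of data rows written.
#' @export
write_timeseries <- function(records, sink) {
  cols <- c("time_h", "n_stem", "n_paneth", "n_enterocyte", "n_goblet",
            "niche_height_cd")
  if (nrow(records) > 0 && !all(cols %in% names(records)))
    stop("records must contain columns: ", paste(cols, collapse = ", "))
  out <- if (nrow(records) == 0) {
    stats::setNames(as.data.frame(matrix(character(0), 0, length(cols)),
                                  stringsAsFactors = FALSE), cols)
  } else {
    as.data.frame(lapply(records[cols], .fmt_full), stringsAsFactors = FALSE,
                  col.names = cols)
  }
  ok <- try(utils::write.table(out, sink, sep = ",", quote = FALSE,
                               row.names = FALSE), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("I/O error writing time series to ", sink)
  nrow(records)
}

#' Read back a time series written by \code{write_timeseries}
#' @param path file path.
#' @return data frame with numeric columns.
#' @export
read_timeseries <- function(path) {
  utils::read.csv(path)
}

#' Write a per-cell snapshot to delimited text
#'
#' One row per live cell, ordered by cell id: id, type label, centroid
#' coordinates (um), element count, and the last recorded Wnt/Notch/BMP
#' exposures. Writing the same state twice yields identical bytes.
#'
#' @param cells a cell table as produced by \code{\link{cell_table}}, or a
#'   simulation state.
#' @param time time in hours recorded in every row.
#' @param sink output path.
#' @return Number of rows written.
#' @export
write_snapshot <- function(cells, time, sink) {
  if (inherits(cells, "crypt_state")) cells <- cell_table(cells)
  cells <- cells[order(cells$cell_id), , drop = FALSE]
  cells$time_h <- rep(time, length.out = nrow(cells))
  cols <- c("time_h", "cell_id", "type", "x", "y", "z", "n_elements",
            "wnt", "notch", "bmp")
  out <- cells[, cols, drop = FALSE]
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], .fmt_full)
  ok <- try(utils::write.table(out, sink, sep = ",", quote = FALSE,
                               row.names = FALSE), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("I/O error writing snapshot to ", sink)
  nrow(out)
}

#' Export element positions as legacy VTK PolyData (points only)
#'
#' Plain-text visualization helper: one VTK point per element with the owning
#' cell's type code as a scalar attribute.
#'
#' @param state a simulation state.
#' @param sink output path.
#' @return \code{sink}, invisibly.
#' @export
write_elements_vtk <- function(state, sink) {
  pos <- state$pos
  n <- nrow(pos)
  con <- file(sink, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "crypt elements", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", n)), con)
  utils::write.table(format(pos, digits = 8), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(c(sprintf("POINT_DATA %d", n), "SCALARS cell_type int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(state$cells$type[state$el_cell]), con)
  invisible(sink)
}
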