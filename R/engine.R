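#' @useDynLib cryptsem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.new_cells_df <- function(n, type, cycle_h, timer_h = 0) {
  data.frame(cell_id = seq_len(n), type = rep(as.integer(type), length.out = n),
             cycle_h = rep(cycle_h, length.out = n),
             timer_h = rep(timer_h, length.out = n),
             life_wk = NA_real_, age_wk = 0, grow_timer_h = 0,
             detached = 0L, wnt = 0, notch = 0, bmp = 0)
}

#' Per-cell summary table of a simulation state
#'
#' @param state a \code{crypt_state}.
#' @return Data frame with one row per live cell: \code{cell_id},
#'   \code{type} (label), centroid \code{x,y,z} (um), \code{n_elements},
#'   and the last recorded \code{wnt}, \code{notch}, \code{bmp} exposures.
#' @export
cell_table <- function(state) {
  geo <- .cell_centroids(state)
  data.frame(cell_id = state$cells$cell_id,
             type = .type_label(state$cells$type),
             x = geo$centroid[, 1], y = geo$centroid[, 2],
             z = geo$centroid[, 3], n_elements = geo$count,
             wnt = state$cells$wnt, notch = state$cells$notch,
             bmp = state$cells$bmp)
}

#' @export
#' @method print crypt_state
print.crypt_state <- function(x, ...) {
  tab <- table(.type_label(x$cells$type))
  cat(sprintf("<crypt_state> t = %.2f h, %d cells (%s), %d elements\n",
              x$time_h, nrow(x$cells),
              paste(names(tab), tab, sep = ":", collapse = " "),
              nrow(x$pos)))
  invisible(x)
}

# rebuild the derived components (force field, grid, calibrated secretion
# rate) after a config change
.refresh_derived <- function(state) {
  cfg <- state$config
  state$field <- force_field(cfg, state$surface)
  if (cfg$wnt_production_pct > 0) {
    if (is.null(state$grid) || state$grid$spacing != cfg$grid_spacing)
      state$grid <- chemical_grid(cfg, state$surface)
    if (is.null(state$rate100))
      state$rate100 <- calibrate_local_rate(state)
    state$rate_per_element <- state$rate100 * cfg$wnt_production_pct / 100
  } else {
    state$rate_per_element <- 0
    if (is.null(state$grid)) state$grid <- NULL
  }
  state
}

# refresh the chemical field from the current Paneth element positions
.chem_update <- function(state, dt_s = NULL) {
  if (is.null(state$grid) || state$rate_per_element <= 0) {
    if (!is.null(state$grid)) state$grid$c <- numeric(prod(state$grid$dim))
    return(state)
  }
  cfg <- state$config
  pan_cells <- which(state$cells$type == CELL_TYPES["PANETH"])
  pan_el <- state$pos[state$el_cell %in% pan_cells, , drop = FALSE]
  src <- deposit_sources(pan_el, state$rate_per_element, state$grid)
  state$grid <- update_diffusivity(state$grid, state$pos)
  if (cfg$chem_mode == "quasi_steady") {
    state$grid <- solve_quasi_steady(state$grid, src, cfg$d_c)
  } else {
    substeps <- as.integer(round(dt_s / cfg$dt_chem))
    state$grid <- step_field(state$grid, src, cfg$dt_chem, substeps, cfg$d_c)
  }
  state
}

#' Generate the canonical crypt initial condition
#'
#' Two identity-free proliferative cells are seeded at the base pole and
#' run under mechanics, growth and division alone (no signaling or fate
#' rules, shortened packing division interval) until daughter cells cover
#' the crypt and the live-cell count saturates. Identities are then
#' assigned canonically: cells below the height at which the deterministic
#' global Wnt gradient crosses the differentiation threshold (about four
#' cell diameters of wall arc in the default geometry) get a stem/Paneth
#' checkerboard (Paneth placed as a greedy maximal independent
#' set of the contact graph, so every stem touches a Paneth), cells above
#' get an enterocyte/Goblet checkerboard. Finally each cell receives a
#' freshly drawn cycle length with a uniformly random elapsed timer and
#' Paneth cells a uniformly random age below their lifetime.
#'
#' @param config a \code{scenario_config}.
#' @param quiet suppress progress messages.
#' @param max_hours packing-iteration cap in simulated hours; exceeding it
#'   is an error.
#' @return A \code{crypt_state} at time 0.
#' @export
initialize_crypt <- function(config = default_config(), quiet = TRUE,
                             max_hours = 300) {
  validate_config(config)
  surface <- crypt_surface(config$crypt_diameter / 2, config$crypt_height)
  R <- surface$R
  N <- config$elements_per_cell

  # seed two identity-free cells just inside the wall near the base pole
  u1 <- c(sin(5 / R), 0, -cos(5 / R))
  u2 <- c(-sin(5 / R), 0, -cos(5 / R))
  c1 <- c(0, 0, R) + (R - 2.5) * u1
  c2 <- c(0, 0, R) + (R - 2.5) * u2
  pos <- rbind(matrix(stats::rnorm(3 * N, sd = 1.2), ncol = 3) +
                 matrix(c1, N, 3, byrow = TRUE),
               matrix(stats::rnorm(3 * N, sd = 1.2), ncol = 3) +
                 matrix(c2, N, 3, byrow = TRUE))
  cells <- .new_cells_df(2, CELL_TYPES["UNASSIGNED"],
                         cycle_h = config$packing_cycle_h *
                           stats::runif(2, 0.9, 1.1))
  cells$timer_h <- stats::runif(2, 0, cells$cycle_h)
  state <- structure(list(
    time_h = 0, pos = pos, el_cell = rep(1:2, each = N), cells = cells,
    next_id = 3L, config = config, surface = surface,
    field = force_field(config, surface), grid = NULL,
    rate_per_element = 0, rate100 = NULL, step_count = 0L),
    class = "crypt_state")

  dt_h <- config$dt_mech / 3600
  k <- as.integer(config$lifecycle_every)
  pack_field <- state$field
  pack_field$paneth_speed <- 0
  history <- integer(0)
  hours <- 0
  repeat {
    state$pos <- integrate_step(state$pos, state$el_cell,
                                rep(FALSE, nrow(state$cells)),
                                pack_field, dt_h, k)
    state <- lifecycle_update(state, k * dt_h, packing = TRUE)
    hours <- hours + k * dt_h
    if (hours > length(history)) {       # record once per simulated hour
      history <- c(history, nrow(state$cells))
      nh <- length(history)
      # covered: the advancing front has reached the rim (no free wall area)
      arcs <- wall_height(surface, .cell_centroids(state)$centroid)
      covered <- max(arcs) >= total_arc(surface) - config$cell_diameter / 2 &&
        nrow(state$cells) >= 2 * total_arc(surface) / config$cell_diameter
      # or the live-cell count has plateaued (turnover balances division)
      plateau <- FALSE
      if (nh >= max(10, 3 * config$packing_cycle_h)) {
        cur <- mean(history[(nh - 4):nh])
        prev <- mean(history[(nh - 9):(nh - 5)])
        plateau <- abs(cur - prev) <= max(2, 0.03 * cur) && history[nh] >= 40
      }
      if (covered || plateau) break
      if (!quiet) message(sprintf("packing: %d h, %d cells", nh, history[nh]))
    }
    if (hours > max_hours)
      stop("crypt packing failed to saturate within ", max_hours,
           " simulated hours")
  }

  # canonical identity assignment
  geo <- .cell_centroids(state)
  arcs <- wall_height(surface, geo$centroid)
  pairs <- contact_neighbors(state$pos, state$el_cell,
                             config$contact_distance)
  ncell <- nrow(state$cells)
  adj <- vector("list", ncell)
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1]; b <- pairs[r, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  # the stem/Paneth zone is where the deterministic global gradient is above
  # threshold (z <= (1 - TH_Wnt) H; about four cell diameters of wall arc in
  # the default geometry)
  geo_z <- geo$centroid[, 3]
  niche <- geo_z <= (1 - config$th_wnt) * config$crypt_height
  type <- integer(ncell)
  for (i in order(arcs)) {
    nb_types <- type[adj[[i]]]
    if (niche[i]) {
      type[i] <- if (any(nb_types == CELL_TYPES["PANETH"]))
        CELL_TYPES["STEM"] else CELL_TYPES["PANETH"]
    } else {
      type[i] <- if (any(nb_types == CELL_TYPES["GOBLET"]))
        CELL_TYPES["ENTEROCYTE"] else CELL_TYPES["GOBLET"]
    }
  }
  state$cells$type <- type
  state$cells$cycle_h <- draw_cycle_length(ncell, config)
  state$cells$timer_h <- stats::runif(ncell) * state$cells$cycle_h
  state$cells$grow_timer_h <- 0
  state$cells$detached <- 0L
  pan <- type == CELL_TYPES["PANETH"]
  state$cells$life_wk[pan] <- draw_paneth_lifetime(sum(pan), config)
  state$cells$age_wk[pan] <- stats::runif(sum(pan)) *
    state$cells$life_wk[pan]
  state$time_h <- 0
  state$step_count <- 0L

  state <- .refresh_derived(state)
  state <- .chem_update(state, dt_s = config$dt_mech)
  # populate the exposure fields without advancing time
  state <- lifecycle_update(state, 0)
  state
}

#' Advance the coupled simulation by mechanical steps
#'
#' Each mechanical step advances element positions by dt_mech (with the
#' configured lifecycle and chemistry cadences interleaved): a mechanics
#' substep, then a lifecycle update (growth, division, fates, removals),
#' then a chemistry update (explicit substeps of dt_chem, or one
#' quasi-steady solve).
#'
#' @param state a \code{crypt_state}.
#' @param n_steps number of mechanical steps (each dt_mech = 3.6 s).
#' @return The advanced state.
#' @export
step_coupled <- function(state, n_steps = 1L) {
  cfg <- state$config
  dt_h <- cfg$dt_mech / 3600
  k <- as.integer(cfg$lifecycle_every)
  kc <- as.integer(cfg$chem_refresh_every)
  done <- 0L
  while (done < n_steps) {
    chunk <- min(k - state$step_count %% k, kc - state$step_count %% kc,
                 n_steps - done)
    paneth <- state$cells$type == CELL_TYPES["PANETH"]
    state$pos <- integrate_step(state$pos, state$el_cell, paneth,
                                state$field, dt_h, chunk)
    state$step_count <- state$step_count + chunk
    state$time_h <- state$time_h + chunk * dt_h
    done <- done + chunk
    if (state$step_count %% k == 0L)
      state <- lifecycle_update(state, k * dt_h)
    if (state$step_count %% kc == 0L)
      state <- .chem_update(state, dt_s = kc * cfg$dt_mech)
  }
  state
}

# record one time-series row
.record_row <- function(state) {
  tab <- tabulate(state$cells$type, nbins = 5)
  data.frame(time_h = state$time_h,
             n_stem = tab[1], n_paneth = tab[2], n_enterocyte = tab[3],
             n_goblet = tab[4],
             niche_height_cd = niche_height(state))
}

#' Run a state forward, recording a time series
#'
#' @param state a \code{crypt_state}.
#' @param hours simulated hours to run.
#' @param record_every_h recording cadence, hours.
#' @return List with the advanced \code{state} and the recorded
#'   \code{series} data frame.
#' @export
run_state <- function(state, hours, record_every_h = 2) {
  cfg <- state$config
  dt_h <- cfg$dt_mech / 3600
  steps_per_rec <- max(1L, as.integer(round(record_every_h / dt_h)))
  total_steps <- as.integer(round(hours / dt_h))
  series <- .record_row(state)
  done <- 0L
  while (done < total_steps) {
    chunk <- min(steps_per_rec, total_steps - done)
    state <- step_coupled(state, chunk)
    done <- done + chunk
    series <- rbind(series, .record_row(state))
  }
  list(state = state, series = series)
}

.scenario_switches <- function(name) {
  switch(name,
    baseline = list(),
    local_wnt_sweep = list(bmp_on = FALSE),
    bmp_sweep = list(bmp_on = TRUE),
    global_wnt_removal = list(bmp_on = TRUE),
    no_paneth_migration_1 = list(paneth_migration_on = FALSE, bmp_on = FALSE,
                                 wnt_production_pct = 0),
    no_paneth_migration_2 = list(paneth_migration_on = FALSE, bmp_on = FALSE,
                                 wnt_production_pct = 100),
    no_paneth_migration_3 = list(paneth_migration_on = FALSE, bmp_on = TRUE,
                                 wnt_production_pct = 100),
    no_paneth_migration_4 = list(paneth_migration_on = FALSE, bmp_on = TRUE,
                                 wnt_production_pct = 200),
    drag_variant = list(),
    fast_cycle = list(cycle_shift_h = 3),
    diffusivity_reduction = list(),
    noise_sweep = list(),
    stop("unknown scenario name: ", name)
  )
}

#' Run one replicate of a named experiment scenario
#'
#' Applies the scenario's switches on top of the configuration and any user
#' overrides, builds (or reuses) the canonical initial condition, and runs
#' for the requested duration. The \code{global_wnt_removal} scenario first
#' runs to a detected steady state (trailing 12 h niche-height slope below
#' 0.05 cell diameters per hour, within \code{pre_days}), then removes the
#' global gradient and runs \code{duration_days} further.
#'
#' @param name one of baseline, local_wnt_sweep, bmp_sweep,
#'   global_wnt_removal, no_paneth_migration_1..4, drag_variant, fast_cycle,
#'   diffusivity_reduction, noise_sweep.
#' @param overrides named list of config overrides (e.g.
#'   \code{wnt_production_pct}).
#' @param duration_days simulated days (after removal, for the removal
#'   scenario).
#' @param seed integer seed; the trajectory is a pure function of
#'   (config, seed).
#' @param init_state optional pre-built initial \code{crypt_state} to reuse
#'   (its cells and elements are kept; config and derived quantities are
#'   replaced).
#' @param record_every_h recording cadence, hours.
#' @param pre_days steady-state search horizon for the removal scenario.
#' @return A \code{scenario_result}: list with \code{series}, \code{final}
#'   (cell table), \code{label} (stability classification, NA for runs
#'   shorter than 2 days), \code{config}, \code{seed}, \code{name}.
#' @export
run_scenario <- function(name, overrides = list(), duration_days = 2,
                         seed = 1L, init_state = NULL, record_every_h = 2,
                         pre_days = 2) {
  sw <- .scenario_switches(name)
  cfg <- load_config(utils::modifyList(sw, overrides))
  set.seed(seed)
  if (is.null(init_state)) {
    state <- initialize_crypt(cfg)
  } else {
    state <- init_state
    state$config <- cfg
    state$rate100 <- NULL
    state$division_log <- NULL
    state <- .refresh_derived(state)
    state <- .chem_update(state, dt_s = cfg$dt_mech)
    state <- lifecycle_update(state, 0)
  }
  series <- NULL
  if (name == "global_wnt_removal") {
    # run to steady state before removing the gradient
    elapsed <- 0
    repeat {
      out <- run_state(state, 12, record_every_h)
      state <- out$state
      series <- if (is.null(series)) out$series else
        rbind(series, out$series[-1, ])
      elapsed <- elapsed + 12
      recent <- series[series$time_h >= elapsed - 12, ]
      slope <- stats::coef(stats::lm(niche_height_cd ~ time_h,
                                     data = recent))[2]
      if (abs(slope) < 0.05 || elapsed >= pre_days * 24) break
    }
    state$config$global_wnt_on <- FALSE
    removal_time <- state$time_h
    out <- run_state(state, duration_days * 24, record_every_h)
    state <- out$state
    series <- rbind(series, out$series[-1, ])
    attr(series, "removal_time_h") <- removal_time
  } else {
    out <- run_state(state, duration_days * 24, record_every_h)
    state <- out$state
    series <- out$series
  }
  total_cd <- total_arc(state$surface) / cfg$cell_diameter
  label <- if (max(series$time_h) - min(series$time_h) >= 48 - 1e-6)
    classify_stability(series$time_h, series$niche_height_cd,
                       series$n_stem, total_cd,
                       slope_thresh = cfg$stability_slope,
                       occupancy = cfg$stability_occupancy)
  else NA_character_
  structure(list(series = series, final = cell_table(state), label = label,
                 config = cfg, seed = seed, name = name, state = state),
            class = "scenario_result")
}

#' @export
#' @method print scenario_result
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> %s (seed %d): %.1f h, final niche %.2f cd, label %s\n",
              x$name, x$seed, max(x$series$time_h),
              x$series$niche_height_cd[nrow(x$series)],
              ifelse(is.na(x$label), "-", x$label)))
  invisible(x)
}

#' Run an ensemble of scenario replicates
#'
#' Replicates use seeds \code{base_seed .. base_seed + n - 1}. Per-time
#' mean and standard deviation of niche height and composition are
#' reported; reruns with the same base seed give identical aggregates.
#'
#' @param name scenario name (see \code{\link{run_scenario}}).
#' @param n number of replicates.
#' @param base_seed first seed.
#' @param ... passed to \code{\link{run_scenario}}.
#' @return List with \code{replicates} (scenario_result list), \code{summary}
#'   (per-time mean/sd data frame), and \code{labels}.
#' @export
run_ensemble <- function(name, n = 10, base_seed = 1L, ...) {
  reps <- lapply(seq_len(n) - 1L, function(i)
    run_scenario(name, seed = base_seed + i, ...))
  times <- reps[[1]]$series$time_h
  hmat <- vapply(reps, function(r) r$series$niche_height_cd[seq_along(times)],
                 numeric(length(times)))
  smat <- vapply(reps, function(r) r$series$n_stem[seq_along(times)],
                 numeric(length(times)))
  hmat <- matrix(hmat, nrow = length(times))
  smat <- matrix(smat, nrow = length(times))
  summary <- data.frame(
    time_h = times,
    niche_mean = rowMeans(hmat),
    niche_sd = apply(hmat, 1, stats::sd),
    stem_mean = rowMeans(smat),
    stem_sd = apply(smat, 1, stats::sd))
  summary$niche_sd[is.na(summary$niche_sd)] <- 0
  summary$stem_sd[is.na(summary$stem_sd)] <- 0
  list(replicates = reps, summary = summary,
       labels = vapply(reps, function(r) as.character(r$label),
                       character(1)))
}

#' Calibrate the Paneth migration speed
#'
#' Bisection on a short baseline run for the smallest downhill speed at
#' which the Paneth population's mean wall height does not rise over the
#' run (the active migration holds station against the proliferative
#' conveyor). Provided for recalibration; the package default (2 um/h) was
#' fixed from the proliferative-flux estimate.
#'
#' @param config a \code{scenario_config}.
#' @param hours length of each probe run.
#' @param lo,hi initial bracket, um/h.
#' @param iters bisection iterations.
#' @param seed RNG seed for the probe runs.
#' @return Calibrated speed, um/h.
#' @export
calibrate_paneth_bias <- function(config = default_config(), hours = 12,
                                  lo = 0, hi = 8, iters = 4, seed = 1L) {
  drift <- function(speed) {
    cfg <- config
    cfg$paneth_bias_speed <- speed
    set.seed(seed)
    state <- initialize_crypt(cfg)
    pan0 <- mean(wall_height(state$surface,
      .cell_centroids(state)$centroid)[state$cells$type == CELL_TYPES["PANETH"]])
    out <- run_state(state, hours, record_every_h = hours)
    st <- out$state
    pan1 <- mean(wall_height(st$surface,
      .cell_centroids(st)$centroid)[st$cells$type == CELL_TYPES["PANETH"]])
    pan1 - pan0
  }
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (drift(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
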