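# Hand-built fixtures: small configurations and states assembled in code.

# reduced geometry + coarse cadences for fast engine tests
mini_config <- function(...) {
  load_config(utils::modifyList(
    list(crypt_height = 60, crypt_diameter = 40,
         lifecycle_every = 50L, chem_refresh_every = 500L,
         grid_spacing = 2.5, chem_mode = "quasi_steady",
         packing_cycle_h = 3, wnt_production_pct = 0),
    list(...)))
}

# a crypt_state built directly from cell centres and types (no packing):
# each cell is a deterministic small element cloud around its centre
make_state <- function(centers, types, config = mini_config(), relax_h = 0) {
  surface <- crypt_surface(config$crypt_diameter / 2, config$crypt_height)
  n <- config$elements_per_cell
  k <- seq_len(n) - 0.5
  th <- acos(1 - 2 * k / n)
  ph <- pi * (1 + sqrt(5)) * k
  cloud <- 1.5 * cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  centers <- matrix(centers, ncol = 3, byrow = FALSE)
  pos <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    sweep(cloud, 2, centers[i, ], "+")))
  types <- unname(CELL_TYPES[types])
  ncell <- length(types)
  cells <- data.frame(
    cell_id = seq_len(ncell), type = as.integer(types),
    cycle_h = 24, timer_h = 0, life_wk = 8, age_wk = 0,
    grow_timer_h = 0, detached = 0L, wnt = 0, notch = 0, bmp = 0)
  state <- structure(list(
    time_h = 0, pos = pos, el_cell = rep(seq_len(ncell), each = n),
    cells = cells, next_id = ncell + 1L, config = config, surface = surface,
    field = force_field(config, surface), grid = NULL,
    rate_per_element = 0, rate100 = NULL, step_count = 0L),
    class = "crypt_state")
  if (relax_h > 0) {
    state$pos <- integrate_step(state$pos, state$el_cell,
                                rep(FALSE, ncell), state$field,
                                1e-3, ceiling(relax_h / 1e-3))
  }
  state
}

# independent all-pairs force oracle in plain R (no neighbor structures)
brute_forces <- function(pos, el_cell, field, surface) {
  n <- nrow(pos)
  f <- matrix(0, n, 3)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- pos[i, ] - pos[j, ]
      r <- sqrt(sum(d^2))
      if (el_cell[i] == el_cell[j]) {
        fij <- -field$mu * (r - field$r0) * d / r
      } else if (r <= field$lj_cutoff) {
        rr <- max(r, 0.5 * field$sigma_lj)
        q6 <- (field$sigma_lj / rr)^6
        fij <- (field$eps_lj / rr) * (12 * q6^2 - 6 * q6) * d / r
      } else {
        fij <- c(0, 0, 0)
      }
      f[i, ] <- f[i, ] + fij
      f[j, ] <- f[j, ] - fij
    }
  }
  for (i in seq_len(n)) {
    q <- surface_query(surface, pos[i, ])
    if (q$distance <= field$wall_cutoff)
      f[i, ] <- f[i, ] + field$eps_external * (q$foot[1, ] - pos[i, ])
  }
  f
}
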