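#' Cell type codes
#'
#' Integer codes used throughout the simulator: 1 STEM, 2 PANETH,
#' 3 ENTEROCYTE, 4 GOBLET, 5 UNASSIGNED (identity-free packing cells).
#' @export
CELL_TYPES <- c(STEM = 1L, PANETH = 2L, ENTEROCYTE = 3L, GOBLET = 4L,
                UNASSIGNED = 5L)

.type_label <- function(code) names(CELL_TYPES)[code]
.type_code <- function(label) {
  if (is.numeric(label)) return(as.integer(label))
  unname(CELL_TYPES[label])
}

#' Notch activation from contacting neighbors
#'
#' A cell's Notch activity is the sum over its contacting neighbors of the
#' ligand weight NP of each neighbor's type: \code{np_paneth} (0.35) for
#' Paneth cells, \code{np_goblet} (1.0) for Goblet cells, zero for all
#' others. A cell whose activity crosses \code{th_notch} is Notch-active.
#'
#' @param neighbor_types types (codes or labels) of the contacting cells.
#' @param config a \code{scenario_config}.
#' @return Notch activation level I_notch.
#' @export
notch_activity <- function(neighbor_types, config = default_config()) {
  codes <- .type_code(neighbor_types)
  sum(ifelse(codes == CELL_TYPES["PANETH"], config$np_paneth,
             ifelse(codes == CELL_TYPES["GOBLET"], config$np_goblet, 0)))
}

#' Contacting cell pairs
#'
#' Two distinct cells are in contact when at least one pair of their
#' elements lies within \code{contact_distance} (default 6 um, just beyond
#' the inter-cell equilibrium separation 2^(1/6) sigma_lj = 5.05 um, so
#' relaxed touching membranes register as contact).
#'
#' @param pos n x 3 element positions.
#' @param el_cell owning cell index per element (1-based).
#' @param contact_distance contact threshold, um.
#' @return Two-column matrix of cell index pairs (each pair once, a < b).
#' @export
contact_neighbors <- function(pos, el_cell, contact_distance = 6.0) {
  cpp_contact_pairs(.as_points(pos), as.integer(el_cell), contact_distance)
}

# Notch activity for every cell at once from the contact pair list: each
# cell receives the ligand weight of every contacting neighbor
.notch_all <- function(pairs, types, ncell, config) {
  np <- numeric(max(CELL_TYPES))
  np[CELL_TYPES["PANETH"]] <- config$np_paneth
  np[CELL_TYPES["GOBLET"]] <- config$np_goblet
  out <- numeric(ncell)
  if (nrow(pairs)) {
    idx <- c(pairs[, 1], pairs[, 2])
    w <- c(np[types[pairs[, 2]]], np[types[pairs[, 1]]])
    s <- tapply(w, idx, sum)
    out[as.integer(names(s))] <- s
  }
  out
}

#' Exogenous morphogen level at a height
#'
#' The mesenchyme-derived Wnt gradient is highest at the crypt base and
#' decreases linearly along the crypt axis, non-dimensionalized to [0,1]:
#' WNT(z) = 1 - z/H. The BMP gradient opposes it: BMP(z) = z/H. Both
#' profiles are clipped to [0,1] and then carry uncorrelated multiplicative
#' Gaussian noise, profile * (1 + sigma * xi), floored at zero; xi is drawn
#' fresh at every evaluation.
#'
#' @param z height(s) above the base pole, um.
#' @param kind "WNT" or "BMP".
#' @param H crypt height, um.
#' @param sigma noise amplitude (>= 0).
#' @return Signal level(s), >= 0.
#' @export
exogenous_signal <- function(z, kind = c("WNT", "BMP"), H = 160, sigma = 0) {
  kind <- match.arg(kind)
  prof <- if (kind == "WNT") 1 - z / H else z / H
  prof <- pmin(pmax(prof, 0), 1)
  if (sigma > 0) prof <- prof * (1 + sigma * stats::rnorm(length(prof)))
  pmax(prof, 0)
}

#' Total Wnt exposure of one cell
#'
#' The sum of the Paneth-derived diffusible field, read as the equal-weight
#' mean of the grid field over the cell's elements, and the exogenous
#' gradient evaluated at the cell centroid height (zero when the global
#' gradient is switched off).
#'
#' @param cell_elements n x 3 positions of the cell's elements.
#' @param grid a \code{chemical_grid}, or NULL for no local field.
#' @param config a \code{scenario_config}.
#' @param surface a \code{crypt_surface} (unused, kept for symmetry).
#' @return I_wnt for the cell.
#' @export
total_wnt <- function(cell_elements, grid, config = default_config(),
                      surface = NULL) {
  cell_elements <- .as_points(cell_elements)
  local <- if (is.null(grid)) 0 else mean(sample_field(grid, cell_elements))
  glob <- if (isTRUE(config$global_wnt_on))
    exogenous_signal(mean(cell_elements[, 3]), "WNT", config$crypt_height,
                     config$noise_sigma_wnt)
  else 0
  local + glob
}

#' Threshold fate rule
#'
#' Joint Wnt/Notch thresholding over the lineage map: a stem cell above the
#' Wnt threshold stays stem if Notch-activated and terminally
#' differentiates into a Paneth cell otherwise; a stem cell below the Wnt
#' threshold differentiates into an enterocyte (Notch-active) or Goblet
#' cell. Paneth identity is absorbing. Differentiated cells transition
#' only reversibly between the Goblet and enterocyte fates according to
#' Notch; stem re-entry (and with it differentiated-to-Paneth conversion)
#' is disabled unless \code{allow_stem_reentry} is set, in which case the
#' raw threshold table applies to every non-Paneth cell.
#'
#' @param type current type(s), code or label.
#' @param I_wnt,I_notch exposure(s).
#' @param config a \code{scenario_config}.
#' @return New type code(s).
#' @export
update_fate <- function(type, I_wnt, I_notch, config = default_config()) {
  cur <- .type_code(type)
  hi_w <- I_wnt >= config$th_wnt
  hi_n <- I_notch >= config$th_notch
  prop <- ifelse(hi_w & hi_n, CELL_TYPES["STEM"],
          ifelse(hi_w & !hi_n, CELL_TYPES["PANETH"],
          ifelse(!hi_w & hi_n, CELL_TYPES["ENTEROCYTE"],
                 CELL_TYPES["GOBLET"])))
  out <- as.integer(prop)
  # Paneth cells never transition out
  out[cur == CELL_TYPES["PANETH"]] <- CELL_TYPES["PANETH"]
  if (!isTRUE(config$allow_stem_reentry)) {
    # differentiated cells only toggle between Goblet and enterocyte;
    # stem and Paneth fates arise from stem cells alone
    diffd <- which(cur %in% CELL_TYPES[c("ENTEROCYTE", "GOBLET")])
    hin <- rep(hi_n, length.out = length(cur))
    out[diffd] <- as.integer(ifelse(hin[diffd], CELL_TYPES["ENTEROCYTE"],
                                    CELL_TYPES["GOBLET"]))
  }
  out
}

# rejection sampler for a truncated normal (bounds are a couple of sd wide,
# so acceptance is high and the loop terminates quickly)
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Draw stem-cell cycle lengths
#'
#' Normal(cycle_mean_h, cycle_sd_h) truncated to \code{cycle_bounds_h}
#' (24 +/- 4 h on [20, 28] by default), minus \code{cycle_shift_h} when the
#' shortened-cycle perturbation is active.
#'
#' @param n number of draws.
#' @param config a \code{scenario_config}.
#' @return Cycle lengths in hours.
#' @export
draw_cycle_length <- function(n, config = default_config()) {
  .rtruncnorm(n, config$cycle_mean_h, config$cycle_sd_h,
              config$cycle_bounds_h[1], config$cycle_bounds_h[2]) -
    config$cycle_shift_h
}

#' Draw Paneth-cell lifetimes
#'
#' Normal(8, 2) weeks truncated to [6, 10] by default.
#'
#' @inheritParams draw_cycle_length
#' @return Lifetimes in weeks.
#' @export
draw_paneth_lifetime <- function(n, config = default_config()) {
  .rtruncnorm(n, config$paneth_life_mean_wk, config$paneth_life_sd_wk,
              config$paneth_life_bounds_wk[1], config$paneth_life_bounds_wk[2])
}

#' Partition a cell's elements across a division plane
#'
#' The division plane contains the local wall normal at the centroid's foot
#' point and a uniformly random azimuthal direction in the tangent plane,
#' so both daughters keep wall contact. Elements are split by the side of
#' the plane through the centroid and rebalanced by moving the elements
#' nearest the plane so the counts differ by at most one.
#'
#' @param pos n x 3 positions of the dividing cell's elements.
#' @param surface a \code{crypt_surface}.
#' @return List with integer index vectors \code{a} and \code{b}
#'   (|length difference| <= 1) and the plane normal \code{m}.
#' @export
split_plane_partition <- function(pos, surface) {
  pos <- .as_points(pos)
  cen <- colMeans(pos)
  q <- surface_query(surface, cen)
  nrm <- q$normal[1, ]
  # orthonormal basis of the tangent plane at the foot
  t1 <- downhill_tangent(surface, cen)[1, ]
  if (sum(t1^2) < 1e-12) {          # at the pole: any tangent direction
    t1 <- c(1, 0, 0)
  }
  t2 <- c(nrm[2] * t1[3] - nrm[3] * t1[2],
          nrm[3] * t1[1] - nrm[1] * t1[3],
          nrm[1] * t1[2] - nrm[2] * t1[1])
  ang <- stats::runif(1, 0, 2 * pi)
  m <- cos(ang) * t1 + sin(ang) * t2   # plane normal: in-tangent direction
  s <- as.numeric(sweep(pos, 2, cen) %*% m)
  ord <- order(s)
  n <- nrow(pos)
  na <- n %/% 2
  list(a = ord[seq_len(na)], b = ord[(na + 1):n], m = m)
}

#' Divide a stem cell of a simulation state
#'
#' Splits the cell across a random division plane perpendicular to the
#' crypt wall; both daughters receive timer zero, freshly drawn cycle
#' lengths, and remain stem pending the next fate update.
#'
#' @param state a \code{crypt_state}.
#' @param cell index of the dividing cell.
#' @param packing internal: allow identity-free packing cells to divide.
#' @return The updated state.
#' @export
divide_cell <- function(state, cell, packing = FALSE) {
  cl <- state$cells
  if (!packing && cl$type[cell] != CELL_TYPES["STEM"])
    stop("only stem cells divide")
  els <- which(state$el_cell == cell)
  if (length(els) < 2) return(state)
  part <- split_plane_partition(state$pos[els, , drop = FALSE], state$surface)
  new_idx <- nrow(cl) + 1L
  state$el_cell[els[part$b]] <- new_idx
  # cytokinesis offset: nudge the daughters apart along the division-plane
  # normal so they start without deep element overlap
  state$pos[els[part$a], ] <- sweep(state$pos[els[part$a], , drop = FALSE],
                                    2, part$m, "-")
  state$pos[els[part$b], ] <- sweep(state$pos[els[part$b], , drop = FALSE],
                                    2, part$m, "+")
  cyc <- if (packing) state$config$packing_cycle_h * stats::runif(2, 0.9, 1.1)
         else draw_cycle_length(2, state$config)
  cl$timer_h[cell] <- 0
  cl$cycle_h[cell] <- cyc[1]
  cl$grow_timer_h[cell] <- 0
  daughter <- cl[cell, , drop = FALSE]
  daughter$cell_id <- state$next_id
  daughter$cycle_h <- cyc[2]
  daughter$detached <- 0L
  rownames(daughter) <- NULL
  state$next_id <- state$next_id + 1L
  state$cells <- rbind(cl, daughter)
  state
}

# per-cell centroids and element counts
.cell_centroids <- function(state) {
  ncell <- nrow(state$cells)
  cnt <- tabulate(state$el_cell, nbins = ncell)
  cen <- rowsum(state$pos, state$el_cell, reorder = TRUE)
  out <- matrix(0, ncell, 3)
  out[as.integer(rownames(cen)), ] <- cen
  list(centroid = out / pmax(cnt, 1), count = cnt)
}

# drop the given cell rows (and their elements), remapping indices
.remove_cells <- function(state, drop_idx) {
  if (!length(drop_idx)) return(state)
  keep <- setdiff(seq_len(nrow(state$cells)), drop_idx)
  remap <- integer(nrow(state$cells))
  remap[keep] <- seq_along(keep)
  el_keep <- state$el_cell %in% keep
  state$pos <- state$pos[el_keep, , drop = FALSE]
  state$el_cell <- remap[state$el_cell[el_keep]]
  state$cells <- state$cells[keep, , drop = FALSE]
  rownames(state$cells) <- NULL
  state
}

#' One lifecycle update of the whole crypt
#'
#' Advances timers by \code{dt_h}, grows cells toward their full element
#' complement (one element per cycle_length/(N/2) hours, placed at the
#' centroid with a small random offset), divides stem cells whose timer has
#' expired and whose BMP exposure is below threshold, updates fates from
#' the current Wnt/Notch exposures, and removes cells that crossed the rim,
#' detached from the wall (after one full update of grace), or exhausted a
#' Paneth lifetime.
#'
#' @param state a \code{crypt_state}.
#' @param dt_h elapsed simulated time since the previous update, hours.
#' @param packing internal: identity-free packing phase (divisions only, no
#'   signaling or fates).
#' @return The updated state; \code{state$last_events} holds the counts of
#'   births, removals, and fate changes.
#' @export
lifecycle_update <- function(state, dt_h, packing = FALSE) {
  cfg <- state$config
  N <- cfg$elements_per_cell
  cl <- state$cells
  ncell0 <- nrow(cl)
  if (ncell0 == 0) return(state)

  # (1) timers
  cl$timer_h <- cl$timer_h + dt_h
  cl$grow_timer_h <- cl$grow_timer_h + dt_h
  pan <- cl$type == CELL_TYPES["PANETH"]
  cl$age_wk[pan] <- cl$age_wk[pan] + dt_h / 168

  # (2) growth
  cnt <- tabulate(state$el_cell, nbins = ncell0)
  interval <- cl$cycle_h / (N / 2)
  grow <- which(cnt < N & cl$grow_timer_h >= interval)
  if (length(grow)) {
    cen <- .cell_centroids(list(pos = state$pos, el_cell = state$el_cell,
                                cells = cl))$centroid
    n_add <- pmin(floor(cl$grow_timer_h[grow] / interval[grow]),
                  N - cnt[grow])
    cl$grow_timer_h[grow] <- cl$grow_timer_h[grow] -
      n_add * interval[grow]
    tot <- sum(n_add)
    newpos <- cen[rep(grow, n_add), , drop = FALSE] +
      matrix(stats::rnorm(3 * tot, sd = 0.5), ncol = 3)
    state$pos <- rbind(state$pos, newpos)
    state$el_cell <- c(state$el_cell, rep(grow, n_add))
  }

  # (3) exposures (skipped during identity-free packing)
  if (!packing) {
    geo <- .cell_centroids(list(pos = state$pos, el_cell = state$el_cell,
                                cells = cl))
    zc <- pmin(pmax(geo$centroid[, 3], 0), cfg$crypt_height)
    pairs <- contact_neighbors(state$pos, state$el_cell,
                               cfg$contact_distance)
    notch <- .notch_all(pairs, cl$type, ncell0, cfg)
    if (!is.null(state$grid) && state$rate_per_element > 0) {
      samp <- sample_field(state$grid, state$pos)
      loc <- numeric(ncell0)
      sums <- rowsum(samp, state$el_cell, reorder = TRUE)
      loc[as.integer(rownames(sums))] <- sums[, 1]
      loc <- loc / pmax(geo$count, 1)
    } else loc <- numeric(ncell0)
    glob <- if (isTRUE(cfg$global_wnt_on))
      exogenous_signal(zc, "WNT", cfg$crypt_height, cfg$noise_sigma_wnt)
    else numeric(ncell0)
    iw <- loc + glob
    ib <- if (isTRUE(cfg$bmp_on))
      exogenous_signal(zc, "BMP", cfg$crypt_height, cfg$noise_sigma_bmp)
    else numeric(ncell0)
    cl$wnt <- iw; cl$notch <- notch; cl$bmp <- ib
  }
  state$cells <- cl

  # (4) divisions
  cnt <- tabulate(state$el_cell, nbins = nrow(state$cells))
  if (packing) {
    # confluence gate: during construction only cells with free space
    # divide, so the crypt fills as a monolayer instead of piling up;
    # crowding is measured by centroids within one cell diameter
    cen <- .cell_centroids(state)$centroid
    nb <- rowSums(as.matrix(stats::dist(cen)) <= cfg$cell_diameter) - 1L
    ready <- which(state$cells$timer_h >= state$cells$cycle_h & cnt >= N &
                   nb <= cfg$pack_crowd_max)
  } else {
    ready <- which(state$cells$type == CELL_TYPES["STEM"] &
                   state$cells$timer_h >= state$cells$cycle_h &
                   cnt >= N &
                   state$cells$bmp < cfg$th_bmp)
  }
  if (length(ready) && !packing) {
    # division log: time and parent centroid height of every division
    zpar <- .cell_centroids(state)$centroid[ready, 3]
    state$division_log <- rbind(state$division_log,
                                data.frame(time_h = state$time_h, z = zpar))
  }
  for (cidx in ready) state <- divide_cell(state, cidx, packing = packing)
  births <- length(ready)

  # (5) fates (pre-division cells only; daughters stay stem until the next
  # update, when fresh exposures exist for them)
  fate_changes <- 0L
  if (!packing) {
    cl <- state$cells
    upd <- seq_len(ncell0)
    newt <- update_fate(cl$type[upd], cl$wnt[upd], cl$notch[upd], cfg)
    became_paneth <- which(newt == CELL_TYPES["PANETH"] &
                           cl$type[upd] != CELL_TYPES["PANETH"])
    fate_changes <- sum(newt != cl$type[upd])
    cl$type[upd] <- newt
    if (length(became_paneth)) {
      cl$life_wk[became_paneth] <- draw_paneth_lifetime(length(became_paneth),
                                                        cfg)
      cl$age_wk[became_paneth] <- 0
    }
    state$cells <- cl
  }

  # (6) removals: rim crossing, detachment (with one update of grace),
  # Paneth lifetime
  geo <- .cell_centroids(state)
  wd <- surface_query(state$surface, state$pos)$distance
  mind <- cpp_group_min(wd, state$el_cell, nrow(state$cells))
  det_now <- mind > cfg$wall_cutoff
  state$cells$detached <- ifelse(det_now, state$cells$detached + 1L, 0L)
  drop_idx <- which(
    geo$centroid[, 3] > cfg$crypt_height |
    state$cells$detached >= 2L |
    (state$cells$type == CELL_TYPES["PANETH"] &
     state$cells$age_wk >= state$cells$life_wk))
  removals <- length(drop_idx)
  state <- .remove_cells(state, drop_idx)

  state$last_events <- list(births = births, removals = removals,
                            fate_changes = fate_changes)
  state
}
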