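#' Mechanical force field parameters
#'
#' Bundles the subcellular-element force constants of a configuration into
#' the parameter set used by the compiled kernels. Under the overdamped
#' dynamics an element's provisional velocity is mobility * F (um/h), with
#' a mobility of 60 um/h per unit force by default, chosen so that cell
#' rearrangement (minutes) is fast compared to the cell cycle (a day) and
#' the epithelium stays a packed monolayer while renewal remains
#' division-limited. Simulated time advances by \code{dt_mech} seconds per
#' mechanical step. Per-step displacements are clamped at
#' \code{max_step_um} so capped short-range repulsion between overlapping,
#' freshly divided cells separates them steadily without overshoot.
#'
#' The short-range inter-cell repulsion is capped at its value at
#' r = 0.5 sigma_lj so freshly divided, overlapping cells separate without
#' numerical blowup. Drag enters the first-order dynamics by rescaling the
#' provisional z-velocity of near-wall elements by (1 + b_z).
#'
#' @param config a \code{scenario_config}.
#' @param surface a \code{crypt_surface}; defaults to the config geometry.
#' @return A named list of class \code{force_field}.
#' @export
force_field <- function(config = default_config(), surface = NULL) {
  if (is.null(surface))
    surface <- crypt_surface(config$crypt_diameter / 2, config$crypt_height)
  ff <- list(
    mu = config$mu, r0 = config$r0,
    eps_lj = config$eps_lj, sigma_lj = config$sigma_lj,
    lj_cutoff = config$lj_cutoff, cap_r = 0.5 * config$sigma_lj,
    eps_external = config$eps_external, wall_cutoff = config$wall_cutoff,
    b_z = config$b_z * config$drag_multiplier,
    mobility = config$mobility, max_step = config$max_step_um,
    paneth_speed = if (isTRUE(config$paneth_migration_on))
      config$paneth_bias_speed else 0,
    R = surface$R, H = surface$H,
    skin = 3.0
  )
  class(ff) <- "force_field"
  ff
}

#' Intra-cell spring force on an element
#'
#' Gradient force of the harmonic pair potential V = mu (r - r0)^2 / 2
#' between two elements of the same cell: attractive beyond the rest length
#' r0, repulsive below it, with no cutoff.
#'
#' @param ri,rj 3-vectors, positions of the two elements (um).
#' @param field a \code{force_field}.
#' @return Force (um/h) on the element at \code{ri}.
#' @export
intra_force <- function(ri, rj, field) {
  d <- ri - rj
  r <- sqrt(sum(d^2))
  if (r < 1e-12) stop("coincident elements: spring direction undefined")
  -field$mu * (r - field$r0) * d / r
}

#' Inter-cell Lennard-Jones force on an element
#'
#' Gradient force of V = eps ((sigma/r)^12 - (sigma/r)^6) between elements
#' of different cells: exactly zero beyond the cutoff, zero at the potential
#' minimum r = 2^(1/6) sigma, repulsive below it and attractive above it.
#' Repulsion is capped at its value at r = 0.5 sigma for near-coincident
#' elements.
#'
#' @inheritParams intra_force
#' @return Force (um/h) on the element at \code{ri}.
#' @export
inter_force <- function(ri, rj, field) {
  d <- ri - rj
  r <- sqrt(sum(d^2))
  if (r > field$lj_cutoff) return(c(0, 0, 0))
  u <- if (r < 1e-12) c(1, 0, 0) else d / r
  rr <- max(r, field$cap_r)
  q6 <- (field$sigma_lj / rr)^6
  (field$eps_lj / rr) * (12 * q6^2 - 6 * q6) * u
}

#' Wall adhesion force on an element
#'
#' Attraction of magnitude eps_external * r toward the nearest wall point
#' for elements within the wall cutoff (half a cell diameter); zero beyond,
#' and zero on the wall itself.
#'
#' @param p 3-vector position (um).
#' @param field a \code{force_field}.
#' @param surface a \code{crypt_surface}.
#' @return Force (um/h).
#' @export
wall_force <- function(p, field, surface) {
  q <- surface_query(surface, p)
  if (q$distance[1] > field$wall_cutoff) return(c(0, 0, 0))
  field$eps_external * (q$foot[1, ] - p)
}

#' Vertical drag force near the wall
#'
#' Linear drag F = b_z v_z opposing vertical motion of near-wall elements
#' (the friction of breaking and re-forming membrane adhesions); x and y
#' components are unaffected, and elements away from the wall feel none.
#'
#' @param v 3-vector velocity (um/h).
#' @param near_wall logical, element within the wall cutoff.
#' @param field a \code{force_field}.
#' @return Force (um/h).
#' @export
drag_force <- function(v, near_wall, field) {
  if (!near_wall) return(c(0, 0, 0))
  c(0, 0, field$b_z * v[3])
}

#' Active downhill migration velocity of Paneth cells
#'
#' Paneth cells move toward the crypt base at \code{paneth_speed} along the
#' local downhill wall tangent; all other cell types (and Paneth cells when
#' migration is switched off) receive zero.
#'
#' @param cell_type type label or code.
#' @param p 3-vector position (um).
#' @param field a \code{force_field}.
#' @param surface a \code{crypt_surface}.
#' @return Velocity contribution (um/h).
#' @export
paneth_bias <- function(cell_type, p, field, surface) {
  if (!.is_paneth(cell_type) || field$paneth_speed == 0) return(c(0, 0, 0))
  field$paneth_speed * downhill_tangent(surface, p)[1, ]
}

.is_paneth <- function(type) {
  if (is.character(type)) type == "PANETH" else type == 2L
}

#' Total potential force on every element
#'
#' Sum of intra-cell spring, inter-cell Lennard-Jones and wall-adhesion
#' forces for all elements (Paneth bias and drag are velocity-level terms
#' applied by the integrator, not potential forces).
#'
#' @param pos n x 3 matrix of element positions (um).
#' @param el_cell integer vector, owning cell index (1-based) per element.
#' @param field a \code{force_field}.
#' @return n x 3 matrix of forces (um/h).
#' @export
compute_forces <- function(pos, el_cell, field) {
  cpp_compute_forces(.as_points(pos), as.integer(el_cell), unclass(field))
}

#' Advance element positions by overdamped forward-Euler steps
#'
#' Each step: potential forces (springs, Lennard-Jones via a skin-based
#' Verlet pair list, wall adhesion) give a provisional velocity, Paneth
#' cells add their downhill bias, near-wall elements have their z-velocity
#' rescaled by (1 + b_z), and positions advance by dt. Elements that cross
#' the rigid wall are projected back onto it. Errors on non-finite forces.
#'
#' @param pos n x 3 matrix of element positions (um).
#' @param el_cell integer vector, owning cell index (1-based) per element.
#' @param paneth logical vector per cell: actively migrating Paneth cell.
#' @param field a \code{force_field}.
#' @param dt_h time step in hours (3.6 s = 1e-3 h per mechanical step).
#' @param nsteps number of steps to take.
#' @return Updated n x 3 position matrix.
#' @export
integrate_step <- function(pos, el_cell, paneth, field, dt_h, nsteps = 1L) {
  cpp_mech_advance(.as_points(pos), as.integer(el_cell), as.logical(paneth),
                   unclass(field), as.integer(nsteps), dt_h)
}

#' Relax an isolated random blob of elements into a cell
#'
#' Helper used for construction and tests: places \code{n} elements
#' normally scattered around a centre and relaxes them under the force
#' field.
#'
#' @param centre 3-vector (um).
#' @param n element count.
#' @param field a \code{force_field}.
#' @param sd scatter of the initial blob (um).
#' @param hours relaxation time (simulated hours).
#' @return n x 3 matrix of relaxed positions.
#' @export
relax_blob <- function(centre, n, field, sd = 1.0, hours = 0.5) {
  pos <- matrix(stats::rnorm(3 * n, sd = sd), ncol = 3, byrow = TRUE) +
    matrix(centre, n, 3, byrow = TRUE)
  steps <- ceiling(hours / 1e-3)
  integrate_step(pos, rep(1L, n), FALSE, field, 1e-3, steps)
}

#' Asphericity of an element cloud
#'
#' Relative spread of the principal radii of gyration: 0 for a perfect
#' sphere. Defined as (max - min) / mean of the square roots of the
#' gyration-tensor eigenvalues.
#'
#' @param pos n x 3 matrix of positions.
#' @return Non-negative scalar.
#' @export
asphericity <- function(pos) {
  q <- sweep(pos, 2, colMeans(pos))
  ev <- sqrt(pmax(eigen(crossprod(q) / nrow(q), symmetric = TRUE)$values, 0))
  (max(ev) - min(ev)) / mean(ev)
}
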