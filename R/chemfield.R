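#' Masked regular grid for the diffusible Wnt field
#'
#' A rectangular box of nodes enclosing the crypt with a margin. Nodes are
#' flagged interior when they lie in the epithelial shell: inside the tube,
#' within one cell diameter of the wall, and below the rim. The diffusible
#' signal cannot cross the basement membrane or enter the lumen, so
#' exterior nodes carry zero diffusivity and zero concentration.
#'
#' @param config a \code{scenario_config}.
#' @param surface a \code{crypt_surface}; defaults to the config geometry.
#' @param spacing node spacing in um; defaults to \code{config$grid_spacing}.
#' @return An object of class \code{chemical_grid} with fields
#'   \code{origin}, \code{spacing}, \code{dim}, \code{mask} (logical per
#'   node), \code{D} (per-node diffusivity, um^2/s), and \code{c}
#'   (concentration per node).
#' @export
chemical_grid <- function(config = default_config(), surface = NULL,
                          spacing = NULL) {
  if (is.null(surface))
    surface <- crypt_surface(config$crypt_diameter / 2, config$crypt_height)
  h <- if (is.null(spacing)) config$grid_spacing else spacing
  m <- config$grid_margin
  R <- surface$R; H <- surface$H
  origin <- c(-R - m, -R - m, -m)
  upper <- c(R + m, R + m, H + m)
  dim <- as.integer(floor((upper - origin) / h) + 1L)
  xs <- origin[1] + h * (seq_len(dim[1]) - 1)
  ys <- origin[2] + h * (seq_len(dim[2]) - 1)
  zs <- origin[3] + h * (seq_len(dim[3]) - 1)
  X <- rep(xs, times = dim[2] * dim[3])
  Y <- rep(rep(ys, each = dim[1]), times = dim[3])
  Z <- rep(zs, each = dim[1] * dim[2])
  # signed inside-distance to the wall (positive in the lumen)
  s <- ifelse(Z > R,
              R - sqrt(X^2 + Y^2),
              R - sqrt(X^2 + Y^2 + (Z - R)^2))
  mask <- s >= 0 & s <= config$cell_diameter & Z <= H
  rho_sat <- config$rho_sat
  if (is.na(rho_sat))
    rho_sat <- 3 * config$elements_per_cell /
      ((4 / 3) * pi * (config$cell_diameter / 2)^3)
  g <- list(origin = origin, spacing = h, dim = dim, mask = mask,
            D = config$D_c * as.numeric(mask),
            c = numeric(prod(dim)),
            D_c = config$D_c, rho_sat = rho_sat)
  class(g) <- "chemical_grid"
  g
}

#' @export
#' @method print chemical_grid
print.chemical_grid <- function(x, ...) {
  cat(sprintf("<chemical_grid> %d x %d x %d nodes at %g um (%d interior)\n",
              x$dim[1], x$dim[2], x$dim[3], x$spacing, sum(x$mask)))
  invisible(x)
}

#' Closed-form 1D steady state of a point Wnt source
#'
#' For production flux P at x = 0 on the half line, diffusivity D and decay
#' delta, the steady state of W_t = D W_xx - delta W with -D W_x(0) = P is
#' W_ss(x) = P / sqrt(delta D) * exp(-sqrt(delta / D) x).
#'
#' @param x distance(s) from the source, um (>= 0).
#' @param cal list with fields \code{D} (um^2/s), \code{delta} (/s) and
#'   \code{P} (flux).
#' @return Concentration(s) at \code{x}.
#' @export
steady_state_1d <- function(x, cal) {
  if (!is.finite(cal$D) || cal$D <= 0 || !is.finite(cal$delta) ||
      cal$delta <= 0)
    stop("D and delta must be positive")
  (cal$P / sqrt(cal$delta * cal$D)) * exp(-sqrt(cal$delta / cal$D) * x)
}

#' Calibrate the base (100\%) Wnt production rate
#'
#' Returns the unique production flux P for which the closed-form 1D steady
#' state reaches the differentiation threshold at the target distance:
#' P = th * sqrt(delta D) * exp(x_star sqrt(delta / D)). With the default
#' constants (D = 10 um^2/s, delta = 1e-3 /s, th = 0.85, x_star = 12.5 um)
#' this is the rate at which a single source holds a neighbor 1.25 cell
#' diameters away exactly at threshold; \code{wnt_production_pct} scales it.
#'
#' @param D diffusivity, um^2/s.
#' @param delta decay rate, /s.
#' @param th threshold concentration (dimensionless).
#' @param x_star target distance, um.
#' @return The production flux P.
#' @export
calibrate_base_production <- function(D = 10, delta = 1e-3, th = 0.85,
                                      x_star = 12.5) {
  stopifnot(D > 0, delta > 0, th > 0, x_star > 0)
  th * sqrt(delta * D) * exp(x_star * sqrt(delta / D))
}

#' Numerical 1D steady-state profile with a flux boundary
#'
#' Second-order finite-difference solve of D W'' - delta W = 0 on [0, L]
#' with ghost-node Neumann condition -D W'(0) = P and W(L) = 0.
#'
#' @param P production flux at x = 0.
#' @param D diffusivity, um^2/s.
#' @param delta decay rate, /s.
#' @param L domain length, um (default ten decay lengths, so the far
#'   Dirichlet condition is inconsequential).
#' @param h node spacing, um.
#' @return data frame with columns \code{x} and \code{W}.
#' @export
solve_steady_1d <- function(P, D, delta, L = 1000, h = 0.1) {
  nx <- as.integer(round(L / h)) + 1L
  x <- h * (seq_len(nx) - 1)
  k <- D / h^2
  # interior: -k W[i-1] + (2k + delta) W[i] - k W[i+1] = 0
  # node 1 (ghost flux): (2k + delta) W[1] - 2k W[2] = 2P/h
  # node nx: W = 0
  A <- Matrix::sparseMatrix(
    i = c(seq_len(nx - 1), 2:(nx - 1), 1:(nx - 2), nx),
    j = c(seq_len(nx - 1), 1:(nx - 2), 2:(nx - 1), nx),
    x = c(rep(2 * k + delta, nx - 1), rep(-k, nx - 2),
          -2 * k, rep(-k, nx - 3), 1),
    dims = c(nx, nx))
  b <- c(2 * P / h, numeric(nx - 1))
  W <- as.numeric(Matrix::solve(A, b))
  data.frame(x = x, W = W)
}

#' Interpolated threshold crossing of a decreasing profile
#'
#' @param x positions (increasing).
#' @param W concentrations.
#' @param th threshold.
#' @return The interpolated x at which W first falls below th, or NA if it
#'   never does (or starts below).
#' @export
threshold_crossing <- function(x, W, th) {
  below <- which(W < th)
  if (!length(below) || below[1] == 1) return(NA_real_)
  i <- below[1]
  x[i - 1] + (x[i] - x[i - 1]) * (W[i - 1] - th) / (W[i - 1] - W[i])
}

#' Deposit element-wise production onto the grid
#'
#' Cloud-in-cell (trilinear) spreading of each secreting element's rate onto
#' its 8 enclosing nodes. The deposited field sums exactly to
#' (number of elements) x \code{rate_per_element}.
#'
#' @param positions n x 3 matrix of secreting element positions (um).
#' @param rate_per_element secretion rate per element.
#' @param grid a \code{chemical_grid}.
#' @return Per-node source field (numeric vector). Errors if a point lies
#'   outside the grid box.
#' @export
deposit_sources <- function(positions, rate_per_element, grid) {
  positions <- .as_points(positions)
  if (nrow(positions) == 0) return(numeric(prod(grid$dim)))
  cpp_trilinear_deposit(positions,
                        rep(rate_per_element, length.out = nrow(positions)),
                        grid$origin, grid$spacing, grid$dim)
}

#' Density-dependent effective diffusivity
#'
#' Cells act as obstacles to the diffusible signal: the local diffusivity
#' decreases linearly with the local element number density and saturates
#' to zero at \code{rho_sat}. The default saturation is three times the
#' nominal in-cell density (N elements per nominal cell volume): the packed
#' epithelium's mean density is itself above the nominal in-cell value
#' (cells compress below their nominal diameter), so saturating at the
#' nominal density would seal the whole shell; at three times it, dense
#' tissue roughly halves the diffusivity and only genuine pile-ups block
#' transport.
#'
#' @param element_density per-node element density, elements/um^3 (>= 0).
#' @param D_c free-medium diffusivity, um^2/s.
#' @param rho_sat saturation density, elements/um^3.
#' @return Per-node diffusivity, um^2/s.
#' @export
effective_diffusivity <- function(element_density, D_c, rho_sat) {
  stopifnot(all(element_density >= 0))
  D_c * pmax(0, 1 - element_density / rho_sat)
}

#' Recompute per-node diffusivity from the current element positions
#'
#' Cloud-in-cell counts of elements around each node are converted to a
#' density (per voxel volume) and mapped through
#' \code{\link{effective_diffusivity}}, then floored at
#' \code{floor_frac * D_c} inside the epithelial shell: crowded tissue
#' slows the signal but never seals it — only the basement membrane and
#' the lumen are impermeable. Without the floor, the nodes inside a
#' secreting Paneth cell's own element cloud saturate to zero diffusivity
#' and trap its entire production at the source. Exterior nodes stay at
#' zero.
#'
#' @param grid a \code{chemical_grid}.
#' @param positions n x 3 matrix of all element positions.
#' @param floor_frac minimum interior diffusivity as a fraction of
#'   \code{D_c}.
#' @return The grid with updated \code{D}.
#' @export
update_diffusivity <- function(grid, positions, floor_frac = 0.2) {
  counts <- cpp_trilinear_deposit(.as_points(positions),
                                  rep(1, nrow(positions)),
                                  grid$origin, grid$spacing, grid$dim)
  dens <- counts / grid$spacing^3
  D <- effective_diffusivity(dens, grid$D_c, grid$rho_sat)
  grid$D <- pmax(D, floor_frac * grid$D_c) * as.numeric(grid$mask)
  grid
}

#' Advance the chemical field by explicit forward-Euler substeps
#'
#' Repeats \code{substeps} times: c <- c + dt (div(D grad c) + S - d_c c),
#' with second-order central differences, harmonic-mean face diffusivities
#' (zero-diffusivity nodes seal their faces), concentrations clamped at
#' zero and exterior nodes held at zero. Refuses to run if the stability
#' bound max(D) dt / h^2 <= 1/6 is violated.
#'
#' @param grid a \code{chemical_grid}.
#' @param sources per-node source field (from \code{\link{deposit_sources}}).
#' @param dt substep length, s.
#' @param substeps number of substeps.
#' @param d_c decay rate, /s.
#' @return The grid with updated \code{c}.
#' @export
step_field <- function(grid, sources, dt, substeps, d_c) {
  ndim <- sum(grid$dim > 1)
  ratio <- max(grid$D) * dt / grid$spacing^2
  if (ratio > 1 / (2 * ndim) + 1e-12)
    stop("explicit stability violated: max(D)*dt/h^2 = ", signif(ratio, 4),
         " > ", signif(1 / (2 * ndim), 3))
  grid$c <- cpp_ftcs(grid$c, grid$D, as.integer(grid$mask), sources,
                     grid$dim, grid$spacing, dt, as.integer(substeps), d_c)
  grid
}

#' Sample the chemical field at arbitrary points
#'
#' Trilinear interpolation of the node concentrations; exact for fields
#' affine in position. Errors for points outside the grid box.
#'
#' @param grid a \code{chemical_grid}.
#' @param p a 3-vector or n x 3 matrix of points (um).
#' @return Concentration(s) at \code{p}.
#' @export
sample_field <- function(grid, p) {
  cpp_trilinear_sample(grid$c, grid$dim, grid$origin, grid$spacing,
                       .as_points(p))
}

#' Solve the quasi-steady chemical field
#'
#' Direct sparse solve of div(D grad c) - d_c c + S = 0 over the interior
#' nodes (7-point stencil, harmonic-mean face diffusivities), used in place
#' of explicit stepping when the field is much faster than the cells (its
#' relaxation time 1/d_c is minutes while lineage dynamics take hours).
#'
#' @inheritParams step_field
#' @return The grid with \code{c} set to the steady state.
#' @export
solve_quasi_steady <- function(grid, sources, d_c) {
  n <- prod(grid$dim)
  nx <- grid$dim[1]; ny <- grid$dim[2]; nz <- grid$dim[3]
  mask <- grid$mask
  idx <- which(mask)
  loc <- integer(n); loc[idx] <- seq_along(idx)   # full -> local unknown id
  h2 <- grid$spacing^2
  ii <- seq_along(idx); jj <- seq_along(idx)
  vv <- rep(d_c, length(idx))
  add <- function(stride, valid_a) {
    a <- which(mask & valid_a)
    b <- a + stride
    keep <- mask[b]
    a <- a[keep]; b <- b[keep]
    Df <- 2 * grid$D[a] * grid$D[b] / (grid$D[a] + grid$D[b])
    Df[!is.finite(Df)] <- 0
    w <- Df / h2
    la <- loc[a]; lb <- loc[b]
    ii <<- c(ii, la, lb, la, lb)
    jj <<- c(jj, la, lb, lb, la)
    vv <<- c(vv, w, w, -w, -w)
  }
  ix <- rep(seq_len(nx), times = ny * nz)
  iy <- rep(rep(seq_len(ny), each = nx), times = nz)
  iz <- rep(seq_len(nz), each = nx * ny)
  add(1L, ix < nx)
  add(nx, iy < ny)
  add(nx * ny, iz < nz)
  A <- Matrix::forceSymmetric(Matrix::sparseMatrix(
    i = ii, j = jj, x = vv, dims = c(length(idx), length(idx))))
  # the sparsity pattern is fixed by the mask, so the symbolic Cholesky
  # analysis can be reused across refreshes (only the values change)
  fac <- grid$chol
  fac <- if (!is.null(fac) && isTRUE(grid$chol_n == length(idx)))
    try(Matrix::update(fac, A, mult = 0), silent = TRUE)
  else NULL
  if (is.null(fac) || inherits(fac, "try-error"))
    fac <- Matrix::Cholesky(A, LDL = FALSE, perm = TRUE)
  grid$chol <- fac
  grid$chol_n <- length(idx)
  sol <- as.numeric(Matrix::solve(fac, sources[idx]))
  cfull <- numeric(n)
  cfull[idx] <- pmax(sol, 0)
  grid$c <- cfull
  grid
}

#' Calibrate the in-crypt local Wnt secretion rate
#'
#' Defines the 100\% production level by its functional meaning in the
#' experiments: at the base rate, the niche's own diffusible Wnt sits just
#' *below* what would sustain its stem cells without the exogenous
#' gradient, and a modest rise in production crosses into the
#' self-sustaining (redundant) regime. Concretely, the quasi-steady field
#' of the state's actual Paneth cells secreting at unit rate is solved on
#' the run's own grid with the run's density-reduced diffusivity, each
#' stem cell's element-averaged exposure is computed exactly as the
#' lifecycle does, and the rate is set so the *median* stem exposure
#' equals \code{th_wnt / margin}. With the default margin of 1.25 (the
#' same margin by which the published 12.5 um calibration distance exceeds
#' one cell diameter), removing the global gradient at the base rate
#' leaves the typical stem cell 25\% short of threshold — the niche
#' collapses — while production at 150--200\% holds it above threshold
#' and the local source alone maintains the niche.
#'
#' The field is linear in the rate, so one sparse solve fixes the scale;
#' the calibration is deterministic given the state. Because it uses the
#' state's own grid, density field and cell configuration, the production
#' axis keeps its meaning across geometries and grid coarsenings.
#'
#' @param state a \code{crypt_state} with assigned identities.
#' @param margin threshold margin at the base rate.
#' @return Per-element secretion rate at the 100\% level (0 if the state
#'   has no Paneth or no stem cells).
#' @export
calibrate_local_rate <- function(state, margin = 1.25) {
  cfg <- state$config
  pan <- which(state$cells$type == CELL_TYPES["PANETH"])
  stems <- which(state$cells$type == CELL_TYPES["STEM"])
  if (!length(pan) || !length(stems)) return(0)
  grid <- chemical_grid(cfg, state$surface)
  grid <- update_diffusivity(grid, state$pos)
  pan_el <- state$pos[state$el_cell %in% pan, , drop = FALSE]
  src <- deposit_sources(pan_el, 1, grid)
  grid <- solve_quasi_steady(grid, src, cfg$d_c)
  samp <- sample_field(grid, state$pos)
  sums <- rowsum(samp, state$el_cell, reorder = TRUE)
  cnt <- tabulate(state$el_cell, nbins = nrow(state$cells))
  expo <- numeric(nrow(state$cells))
  expo[as.integer(rownames(sums))] <- sums[, 1]
  expo <- expo / pmax(cnt, 1)
  med <- stats::median(expo[stems])
  if (med <= 0) stop("calibration failed: zero field at the stem cells")
  (cfg$th_wnt / margin) / med
}
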