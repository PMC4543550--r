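test_that("closed-form 1D steady state behaves as an exponential", {
  cal <- list(D = 10, delta = 1e-3, P = 0.2)
  expect_equal(steady_state_1d(0, cal), 0.2 / sqrt(1e-3 * 10))
  ell <- sqrt(10 / 1e-3)                 # decay length, 100 um
  expect_equal(ell, 100)
  expect_equal(steady_state_1d(ell, cal), steady_state_1d(0, cal) * exp(-1))
  expect_error(steady_state_1d(1, list(D = -1, delta = 1e-3, P = 1)),
               "positive")
})

test_that("base-production calibration hits the threshold at 12.5 um", {
  P <- calibrate_base_production(10, 1e-3, 0.85, 12.5)
  expect_equal(P, 0.85 * 0.1 * exp(0.125))             # ~0.0963
  expect_equal(P, 0.0963176, tolerance = 1e-6)
  cal <- list(D = 10, delta = 1e-3, P = P)
  expect_equal(steady_state_1d(12.5, cal), 0.85)
  # linear in the threshold
  expect_equal(calibrate_base_production(10, 1e-3, 1.7, 12.5), 2 * P)
  # numerical steady-state solver recovers the threshold within 0.5%
  prof <- solve_steady_1d(P, 10, 1e-3)
  w125 <- approx(prof$x, prof$W, 12.5)$y
  expect_equal(w125, 0.85, tolerance = 0.005)
  expect_equal(threshold_crossing(prof$x, prof$W, 0.85), 12.5,
               tolerance = 0.01)
})

test_that("explicit 1D stepping converges to the closed form within 2%", {
  P <- calibrate_base_production()
  h <- 2
  nx <- 301L    # 6 decay lengths, so the sealed far boundary is negligible
  grid <- list(origin = c(0, 0, 0), spacing = h, dim = c(nx, 1L, 1L),
               mask = rep(TRUE, nx), D = rep(10, nx), c = numeric(nx),
               D_c = 10, rho_sat = 1)
  class(grid) <- "chemical_grid"
  src <- numeric(nx); src[1] <- P / h   # boundary flux into the first node
  dt <- 0.18                            # D dt / h^2 = 0.45 < 0.5 (1D)
  for (i in 1:25) grid <- step_field(grid, src, dt, 2000L, 1e-3)
  x <- h * (seq_len(nx) - 1)
  exact <- steady_state_1d(x, list(D = 10, delta = 1e-3, P = P))
  idx <- x > 0 & x <= 300
  expect_lt(max(abs(grid$c[idx] - exact[idx]) / exact[idx]), 0.02)
})

test_that("deposition conserves total rate and uses trilinear weights", {
  cfg <- mini_config()
  grid <- chemical_grid(cfg)
  # element exactly on a node: all weight on that node
  node <- grid$origin + grid$spacing * c(8, 8, 8)
  f <- deposit_sources(rbind(node), 0.01, grid)
  expect_equal(sum(f), 0.01)
  expect_equal(max(f), 0.01)
  # element at a voxel centre: 1/8 on each of 8 nodes
  f <- deposit_sources(rbind(node + grid$spacing / 2), 0.01, grid)
  expect_equal(sort(f[f > 0]), rep(0.01 / 8, 8))
  # exact conservation for many elements
  set.seed(21)
  pts <- cbind(runif(30, -10, 10), runif(30, -10, 10), runif(30, 0, 30))
  expect_equal(sum(deposit_sources(pts, 0.01, grid)), 0.3)
  # outside the box errors
  expect_error(deposit_sources(rbind(c(1e4, 0, 0)), 0.01, grid), "outside")
})

test_that("effective diffusivity ramps down linearly and saturates", {
  expect_equal(effective_diffusivity(0, 10, 0.04), 10)
  expect_equal(effective_diffusivity(0.02, 10, 0.04), 5)
  expect_equal(effective_diffusivity(0.04, 10, 0.04), 0)
  expect_equal(effective_diffusivity(1, 10, 0.04), 0)
})

test_that("explicit stepping decays, accumulates sources, seals exterior", {
  cfg <- mini_config()
  grid <- chemical_grid(cfg, spacing = 2.5)
  inter <- which(grid$mask)
  # uniform field, no sources: one substep of pure decay
  grid$c[inter] <- 1
  g2 <- step_field(grid, numeric(prod(grid$dim)), 0.01, 1L, 1e-3)
  expect_equal(g2$c[inter], rep(1 - 0.01 * 1e-3, length(inter)))
  expect_true(all(g2$c[-inter] == 0))
  # single interior source node, zero field: holds S*dt after one substep
  src <- numeric(prod(grid$dim)); src[inter[100]] <- 0.5
  grid$c[] <- 0
  g3 <- step_field(grid, src, 0.01, 1L, 1e-3)
  expect_equal(g3$c[inter[100]], 0.5 * 0.01)
  expect_equal(sum(g3$c), 0.5 * 0.01)
  # stability refusal
  expect_error(step_field(grid, src, 10, 1L, 1e-3), "stability")
})

test_that("mass is conserved without decay or sources", {
  cfg <- mini_config()
  grid <- chemical_grid(cfg, spacing = 2.5)
  inter <- which(grid$mask)
  set.seed(22)
  grid$c[inter] <- runif(length(inter))
  m0 <- sum(grid$c)
  g <- step_field(grid, numeric(prod(grid$dim)), 0.1, 200L, 0)
  expect_equal(sum(g$c), m0, tolerance = 1e-10)
})

test_that("trilinear sampling is exact on affine fields", {
  cfg <- mini_config()
  grid <- chemical_grid(cfg, spacing = 2.5)
  nx <- grid$dim[1]; ny <- grid$dim[2]; nz <- grid$dim[3]
  xs <- grid$origin[1] + grid$spacing * (seq_len(nx) - 1)
  ys <- grid$origin[2] + grid$spacing * (seq_len(ny) - 1)
  zs <- grid$origin[3] + grid$spacing * (seq_len(nz) - 1)
  X <- rep(xs, times = ny * nz)
  Y <- rep(rep(ys, each = nx), times = nz)
  Z <- rep(zs, each = nx * ny)
  grid$c <- 0.3 + 0.01 * X - 0.02 * Y + 0.005 * Z
  set.seed(23)
  pts <- cbind(runif(40, -15, 15), runif(40, -15, 15), runif(40, 0, 50))
  want <- 0.3 + 0.01 * pts[, 1] - 0.02 * pts[, 2] + 0.005 * pts[, 3]
  expect_equal(sample_field(grid, pts), want, tolerance = 1e-12)
  # node value at a node; constant patch at a voxel centre
  expect_equal(sample_field(grid, rbind(c(xs[3], ys[4], zs[5]))),
               grid$c[3 + nx * (3 + ny * 4)])
  expect_error(sample_field(grid, rbind(c(1e4, 0, 0))), "outside")
})

test_that("quasi-steady solve matches the explicit long-time field", {
  cfg <- mini_config()
  grid <- chemical_grid(cfg, spacing = 2.5)
  # one Paneth-cell-like source mid-crypt on the wall
  p0 <- c(0, -(20 - 2.5), 30)
  set.seed(24)
  els <- matrix(rnorm(60, sd = 1.5), ncol = 3) +
    matrix(p0, 20, 3, byrow = TRUE)
  src <- deposit_sources(els, 0.05, grid)
  qs <- solve_quasi_steady(grid, src, 1e-3)
  ex <- grid
  dt <- 0.1                                # stability: 10*0.1/6.25 = 0.16
  ex <- step_field(ex, src, dt, 60000L, 1e-3)   # 6000 s >> 1/d_c
  inter <- which(grid$mask & qs$c > 0.05 * max(qs$c))
  expect_lt(max(abs(ex$c[inter] - qs$c[inter])) / max(qs$c), 0.03)
})

test_that("raising diffusivity or decay lowers concentration at 12.5 um", {
  base <- list(D = 10, delta = 1e-3, P = 0.1)
  w0 <- steady_state_1d(12.5, base)
  for (f in c(1.5, 3, 10)) {
    expect_lt(steady_state_1d(12.5, utils::modifyList(base, list(D = 10 * f))), w0)
    expect_lt(steady_state_1d(12.5, utils::modifyList(base, list(delta = 1e-3 * f))), w0)
  }
  # and in the 3D solver: a single source, higher D or d, lower nearby field
  cfg <- mini_config()
  grid <- chemical_grid(cfg, spacing = 2.5)
  p0 <- c(0, -(20 - 2.5), 30)
  src <- deposit_sources(rbind(p0), 1, grid)
  probe <- rbind(p0 + c(0, 0, 12.5))   # 12.5 um up the wall from the source
  c_base <- sample_field(solve_quasi_steady(grid, src, 1e-3), probe)
  gD <- grid; gD$D <- gD$D * 3
  c_hiD <- sample_field(solve_quasi_steady(gD, src, 1e-3), probe)
  c_hid <- sample_field(solve_quasi_steady(grid, src, 3e-3), probe)
  expect_lt(c_hiD, c_base)
  expect_lt(c_hid, c_base)
})
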