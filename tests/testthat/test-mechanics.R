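cfg <- default_config()
surf <- crypt_surface(30, 160)
ff <- force_field(cfg, surf)

test_that("intra-cell spring force matches hand evaluation", {
  expect_equal(intra_force(c(0, 0, 0), c(1.5, 0, 0), ff), c(0, 0, 0))
  f <- intra_force(c(0, 0, 0), c(2.5, 0, 0), ff)
  expect_equal(f, c(2.5, 0, 0))          # attractive toward the partner
  f <- intra_force(c(0, 0, 0), c(1.0, 0, 0), ff)
  expect_equal(f, c(-1.25, 0, 0))        # repulsive below rest length
  expect_error(intra_force(c(1, 1, 1), c(1, 1, 1), ff), "coincident")
})

test_that("inter-cell force is zero at the potential minimum and cutoff", {
  rmin <- 2^(1 / 6) * 4.5
  expect_equal(inter_force(c(0, 0, 0), c(rmin, 0, 0), ff), c(0, 0, 0),
               tolerance = 1e-12)
  expect_equal(inter_force(c(0, 0, 0), c(10.5, 0, 0), ff), c(0, 0, 0))
  # repulsive below the minimum, attractive above it (up to the cutoff)
  expect_gt(inter_force(c(0, 0, 0), c(4.0, 0, 0), ff)[1] * -1, 0)
  expect_gt(inter_force(c(0, 0, 0), c(6.0, 0, 0), ff)[1], 0)
  # capped repulsion for overlapping elements
  fcap <- inter_force(c(0, 0, 0), c(0.5 * 4.5, 0, 0), ff)
  fover <- inter_force(c(0, 0, 0), c(0.1, 0, 0), ff)
  expect_equal(sqrt(sum(fover^2)), sqrt(sum(fcap^2)))
})

test_that("wall adhesion force is linear within the cutoff and zero beyond", {
  p <- c(30 - 6, 0, 100)                 # 6 um from the wall
  expect_equal(wall_force(p, ff, surf), c(0, 0, 0))
  p <- c(30 - 2, 0, 100)                 # 2 um from the wall
  f <- wall_force(p, ff, surf)
  expect_equal(f, c(0.001 * 2, 0, 0))    # magnitude eps * r, toward the wall
  expect_equal(wall_force(c(30, 0, 100), ff, surf), c(0, 0, 0))
})

test_that("drag acts on the z component of near-wall elements only", {
  expect_equal(drag_force(c(0, 0, 0), TRUE, ff), c(0, 0, 0))
  expect_equal(drag_force(c(0, 0, 1), TRUE, ff), c(0, 0, -0.3))
  expect_equal(drag_force(c(1, 0, 0), TRUE, ff), c(0, 0, 0))
  expect_equal(drag_force(c(0, 0, 1), FALSE, ff), c(0, 0, 0))
})

test_that("Paneth bias is downhill for Paneth cells and zero otherwise", {
  expect_equal(paneth_bias("STEM", c(30, 0, 100), ff, surf), c(0, 0, 0))
  expect_equal(paneth_bias("PANETH", c(30, 0, 100), ff, surf),
               c(0, 0, -ff$paneth_speed))
  expect_equal(paneth_bias("PANETH", c(0, 0, 0), ff, surf), c(0, 0, 0))
  ff_off <- force_field(load_config(list(paneth_migration_on = FALSE)), surf)
  expect_equal(paneth_bias("PANETH", c(30, 0, 100), ff_off, surf),
               c(0, 0, 0))
})

test_that("pairwise forces obey Newton's third law", {
  set.seed(11)
  # two cells of five elements each, random positions near the base
  pos <- matrix(rnorm(30, sd = 3), ncol = 3) +
    matrix(c(0, 0, 8), 10, 3, byrow = TRUE)
  f <- compute_forces(pos, rep(1:2, each = 5), ff)
  # remove the wall contribution to isolate the pair interactions
  for (i in 1:10) {
    q <- surface_query(surf, pos[i, ])
    if (q$distance <= ff$wall_cutoff)
      f[i, ] <- f[i, ] - ff$eps_external * (q$foot[1, ] - pos[i, ])
  }
  expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-10)
})

test_that("cell-list forces equal the brute-force all-pairs oracle", {
  set.seed(12)
  for (rep in 1:3) {
    ncell <- 8
    centers <- cbind(runif(ncell, -15, 15), runif(ncell, -15, 15),
                     runif(ncell, 5, 40))
    pos <- do.call(rbind, lapply(seq_len(ncell), function(i)
      matrix(rnorm(3 * 20, sd = 2), ncol = 3) +
        matrix(centers[i, ], 20, 3, byrow = TRUE)))   # 160 elements
    el_cell <- rep(seq_len(ncell), each = 20)
    expect_equal(compute_forces(pos, el_cell, ff),
                 brute_forces(pos, el_cell, ff, surf),
                 tolerance = 1e-10)
  }
})

test_that("an isolated cell relaxes from a random blob to a sphere", {
  set.seed(13)
  blob <- relax_blob(c(0, 0, 80), 20, ff, sd = 3, hours = 1)
  expect_lt(asphericity(blob), 0.1)
})

test_that("a relaxed two-cell pair keeps inter-cell separation", {
  set.seed(14)
  pos <- rbind(relax_blob(c(0, 0, 77), 20, ff, sd = 1.5, hours = 0.5),
               relax_blob(c(7, 0, 83), 20, ff, sd = 1.5, hours = 0.5))
  el_cell <- rep(1:2, each = 20)
  pos <- integrate_step(pos, el_cell, c(FALSE, FALSE), ff, 1e-3, 1000)
  d <- as.matrix(dist(pos))[1:20, 21:40]
  expect_gte(min(d), 0.8 * ff$sigma_lj)
})

test_that("incremental pair-list maintenance matches a fresh rebuild", {
  # after a long single call (which maintains its Verlet list
  # incrementally), one further step must equal a step taken from a fresh
  # call (which rebuilds the list from scratch) to floating-point noise
  set.seed(15)
  ncell <- 24
  centers <- cbind(runif(ncell, -18, 18), runif(ncell, -18, 18),
                   runif(ncell, 5, 60))
  pos0 <- do.call(rbind, lapply(seq_len(ncell), function(i)
    matrix(rnorm(60, sd = 1.6), ncol = 3) +
      matrix(centers[i, ], 20, 3, byrow = TRUE)))
  el <- rep(seq_len(ncell), each = 20)
  pa <- integrate_step(pos0, el, rep(FALSE, ncell), ff, 1e-3, 300)
  pb <- integrate_step(pos0, el, rep(FALSE, ncell), ff, 1e-3, 301)
  ref <- integrate_step(pa, el, rep(FALSE, ncell), ff, 1e-3, 1)
  expect_lt(max(abs(pb - ref)), 1e-9)
})

test_that("integration has the expected fixed points and monotone approach", {
  # all forces zero -> stationary (far from wall, two elements at r0)
  pos <- rbind(c(0, 0, 80), c(1.5, 0, 80))
  out <- integrate_step(pos, c(1L, 1L), FALSE, ff, 1e-3, 100)
  expect_equal(out, pos, tolerance = 1e-12)
  # two same-cell elements at r = 2.5 approach r0 monotonically
  pos <- rbind(c(0, 0, 80), c(2.5, 0, 80))
  seps <- numeric(20)
  for (i in 1:20) {
    pos <- integrate_step(pos, c(1L, 1L), FALSE, ff, 1e-3, 2)
    seps[i] <- sqrt(sum((pos[1, ] - pos[2, ])^2))
  }
  expect_true(all(diff(c(2.5, seps)) < 0))
  expect_true(all(seps > ff$r0))
  # matches the 1D ODE r' = -2 mu mobility (r - r0) integrated with the
  # same forward-Euler step (closed form of the linear recurrence)
  fac <- (1 - 2 * ff$mu * ff$mobility * 1e-3)^(2 * (1:20))
  expect_equal(seps, 1.5 + 1.0 * fac, tolerance = 1e-6)
})
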