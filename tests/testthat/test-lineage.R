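cfg <- default_config()

test_that("Notch activation sums ligand weights of contacting neighbors", {
  expect_equal(notch_activity(c("PANETH", "PANETH"), cfg), 0.70)
  expect_equal(notch_activity("GOBLET", cfg), 1.0)
  expect_equal(notch_activity(c("STEM", "ENTEROCYTE", "STEM"), cfg), 0)
  expect_equal(notch_activity(character(0), cfg), 0)
})

test_that("contact detection follows the element-distance threshold", {
  # two 2-element cells whose nearest elements are 4.0 um apart: in contact
  pos <- rbind(c(0, 0, 50), c(1, 0, 50), c(5, 0, 50), c(7, 0, 50))
  pairs <- contact_neighbors(pos, c(1L, 1L, 2L, 2L), 4.5)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs[1, ], c(1L, 2L))
  # nearest pair at 12 um: not in contact; a cell never contacts itself
  pos2 <- rbind(c(0, 0, 50), c(1, 0, 50), c(13, 0, 50), c(15, 0, 50))
  expect_equal(nrow(contact_neighbors(pos2, c(1L, 1L, 2L, 2L), 4.5)), 0)
})

test_that("exogenous gradients have the right endpoints and slopes", {
  expect_equal(exogenous_signal(0, "WNT", 160, 0), 1.0)
  expect_equal(exogenous_signal(160, "WNT", 160, 0), 0.0)
  expect_equal(exogenous_signal(0, "BMP", 160, 0), 0.0)
  expect_equal(exogenous_signal(160, "BMP", 160, 0), 1.0)
  # the Wnt gradient crosses the differentiation threshold at z = 24 um
  expect_equal(exogenous_signal(24, "WNT", 160, 0), 0.85)
  # monotone and clipped
  z <- seq(0, 160, by = 8)
  expect_true(all(diff(exogenous_signal(z, "WNT", 160, 0)) < 0))
  expect_true(all(diff(exogenous_signal(z, "BMP", 160, 0)) > 0))
  # with global gradient only, the above-threshold set is exactly z <= 24
  z <- seq(0, 160, by = 0.5)
  expect_equal(z[exogenous_signal(z, "WNT", 160, 0) >= 0.85], z[z <= 24])
})

test_that("multiplicative gradient noise is seeded and floored at zero", {
  set.seed(5)
  a <- exogenous_signal(rep(80, 100), "WNT", 160, 0.4)
  set.seed(5)
  b <- exogenous_signal(rep(80, 100), "WNT", 160, 0.4)
  expect_identical(a, b)
  expect_true(all(a >= 0))
  expect_gt(stats::sd(a), 0)
})

test_that("total Wnt adds the local field mean and the global gradient", {
  mini <- mini_config()
  grid <- chemical_grid(mini, spacing = 2.5)
  els <- matrix(rnorm(60, sd = 1), ncol = 3) +
    matrix(c(0, -16, 10), 20, 3, byrow = TRUE)
  # zero field, centroid at the base: gradient only
  base_els <- sweep(els, 2, c(0, -16, 10) - colMeans(els), "+")
  expect_equal(total_wnt(sweep(base_els, 2, c(0, 16 - 16, -10), "+"),
                         grid, mini),
               1.0, tolerance = 1e-9)
  # global off, uniform local field: local only
  grid$c[] <- 0.9
  off <- mini; off$global_wnt_on <- FALSE
  expect_equal(total_wnt(els, grid, off), 0.9, tolerance = 1e-12)
  # both: sum of the parts
  both <- total_wnt(els, grid, mini)
  zc <- mean(els[, 3])
  expect_equal(both, 0.9 + (1 - zc / mini$crypt_height), tolerance = 1e-9)
})

test_that("fate table matches a brute-force reimplementation everywhere", {
  # independent restatement of the rule: the threshold table drives stem
  # cells; Paneth is absorbing; differentiated cells only toggle between
  # the Goblet and enterocyte fates with Notch
  oracle <- function(type, iw, in_, cfg) {
    if (type == "PANETH") return("PANETH")
    if (type %in% c("ENTEROCYTE", "GOBLET"))
      return(if (in_ >= cfg$th_notch) "ENTEROCYTE" else "GOBLET")
    if (iw >= cfg$th_wnt) {
      if (in_ >= cfg$th_notch) "STEM" else "PANETH"
    } else {
      if (in_ >= cfg$th_notch) "ENTEROCYTE" else "GOBLET"
    }
  }
  grid_iw <- c(0, 0.3, 0.8499, 0.85, 0.9, 2)
  grid_in <- c(0, 0.2999, 0.3, 0.35, 0.7, 1.2)
  for (type in c("STEM", "PANETH", "ENTEROCYTE", "GOBLET")) {
    for (iw in grid_iw) for (in_ in grid_in) {
      got <- update_fate(type, iw, in_, cfg)
      expect_identical(names(CELL_TYPES)[got], oracle(type, iw, in_, cfg),
                       label = sprintf("%s iw=%g in=%g", type, iw, in_))
    }
  }
  # spot examples
  expect_equal(update_fate("STEM", 0.9, 0.7, cfg), unname(CELL_TYPES["STEM"]))
  expect_equal(update_fate("STEM", 0.9, 0.0, cfg),
               unname(CELL_TYPES["PANETH"]))
  expect_equal(update_fate("GOBLET", 0.5, 1.0, cfg),
               unname(CELL_TYPES["ENTEROCYTE"]))
  expect_equal(update_fate("PANETH", 0.1, 0.0, cfg),
               unname(CELL_TYPES["PANETH"]))
  # with re-entry enabled the raw table applies
  cfg2 <- load_config(list(allow_stem_reentry = TRUE))
  expect_equal(update_fate("GOBLET", 0.9, 0.7, cfg2),
               unname(CELL_TYPES["STEM"]))
})

test_that("truncated samplers respect bounds, means, and the analytic CDF", {
  set.seed(31)
  cyc <- draw_cycle_length(1e5, cfg)
  expect_true(all(cyc >= 20 & cyc <= 28))
  expect_equal(mean(cyc), 24, tolerance = 0.05 / 24)
  expect_lt(abs(mean(cyc) - 24), 0.05)
  life <- draw_paneth_lifetime(1e5, cfg)
  expect_true(all(life >= 6 & life <= 10))
  expect_lt(abs(mean(life) - 8), 0.05)
  # Kolmogorov-Smirnov against the analytic truncated-normal CDF
  ptrunc <- function(q, m, s, a, b)
    (pnorm(q, m, s) - pnorm(a, m, s)) / (pnorm(b, m, s) - pnorm(a, m, s))
  ks <- suppressWarnings(stats::ks.test(cyc, function(q)
    ptrunc(q, 24, 4, 20, 28)))
  expect_gt(ks$p.value, 0.01)
  ks2 <- suppressWarnings(stats::ks.test(life, function(q)
    ptrunc(q, 8, 2, 6, 10)))
  expect_gt(ks2$p.value, 0.01)
  # determinism
  set.seed(99); a <- draw_cycle_length(100, cfg)
  set.seed(99); b <- draw_cycle_length(100, cfg)
  expect_identical(a, b)
  # the shortened-cycle perturbation shifts the whole distribution
  cfg3 <- load_config(list(cycle_shift_h = 3))
  set.seed(99); s <- draw_cycle_length(100, cfg3)
  expect_equal(s, b - 3)
})

test_that("division partitions elements evenly across a wall-normal plane", {
  surf <- crypt_surface(30, 160)
  set.seed(41)
  for (n in c(20, 21)) {
    pos <- matrix(rnorm(3 * n, sd = 2), ncol = 3) +
      matrix(c(0, -27, 60), n, 3, byrow = TRUE)
    part <- split_plane_partition(pos, surf)
    expect_lte(abs(length(part$a) - length(part$b)), 1)
    expect_setequal(c(part$a, part$b), seq_len(n))
    # the plane contains the wall normal: its normal is tangent to the wall
    nrm <- surface_query(surf, colMeans(pos))$normal[1, ]
    expect_lt(abs(sum(part$m * nrm)), 1e-9)
    # both daughters keep elements near the wall side of the parent cloud
    da <- min(surface_query(surf, pos[part$a, ])$distance)
    db <- min(surface_query(surf, pos[part$b, ])$distance)
    expect_lt(max(da, db), min(surface_query(surf, pos)$distance) + 6)
  }
})

test_that("only stem cells divide; daughters reset their clocks", {
  st <- make_state(rbind(c(0, 0, 3), c(8, 0, 5)), c("STEM", "GOBLET"))
  expect_error(divide_cell(st, 2), "stem")
  set.seed(42)
  st$cells$timer_h[1] <- 30
  st2 <- divide_cell(st, 1)
  expect_equal(nrow(st2$cells), 3)
  expect_equal(sum(st2$el_cell == 1), 10)
  expect_equal(sum(st2$el_cell == 3), 10)
  expect_equal(st2$cells$timer_h[c(1, 3)], c(0, 0))
  expect_true(all(st2$cells$cycle_h[c(1, 3)] >= 17))
})

test_that("lifecycle gates division on BMP and removes by the stated rules", {
  mini <- mini_config()
  H <- mini$crypt_height
  # stem low in the crypt (BMP below threshold): divides when timer expires
  st <- make_state(rbind(c(0, 0, 3), c(7, 0, 6)), c("STEM", "PANETH"),
                   config = mini)
  st$cells$timer_h <- c(25, 0)
  st$cells$cycle_h <- c(24, 24)
  set.seed(43)
  st2 <- lifecycle_update(st, 0.1)
  expect_equal(st2$last_events$births, 1)
  expect_equal(nrow(st2$cells), 3)
  # bookkeeping: cells(t+dt) = cells(t) + births - removals
  expect_equal(nrow(st2$cells),
               nrow(st$cells) + st2$last_events$births -
                 st2$last_events$removals)

  # stem high in the crypt: BMP blocks division (z/H = 0.5 >= 0.15) --
  # place at mid-height on the wall; it keeps its stem identity blocked
  zhi <- 0.5 * H
  rwall <- mini$crypt_diameter / 2 - 2.5
  st <- make_state(rbind(c(rwall, 0, zhi), c(rwall - 7, 0, zhi + 2)),
                   c("STEM", "PANETH"), config = mini)
  st$cells$timer_h <- c(25, 0)
  st$cells$cycle_h <- c(24, 24)
  set.seed(44)
  st2 <- lifecycle_update(st, 0.1)
  expect_equal(st2$last_events$births, 0)

  # Paneth cell past its lifetime is removed
  st <- make_state(rbind(c(0, 0, 3), c(7, 0, 6)), c("STEM", "PANETH"),
                   config = mini)
  st$cells$life_wk[2] <- 10
  st$cells$age_wk[2] <- 10.1
  set.seed(45)
  st2 <- lifecycle_update(st, 0.1)
  expect_equal(st2$last_events$removals, 1)
  expect_false(2 %in% st2$cells$cell_id)

  # a cell over the rim is removed immediately; a detached cell only after
  # the one-update grace
  st <- make_state(rbind(c(0, 0, 3), c(0, 0, H + 8)), c("STEM", "ENTEROCYTE"),
                   config = mini)
  set.seed(46)
  st2 <- lifecycle_update(st, 0.1)
  expect_equal(nrow(st2$cells), 1)
  mid <- c(0, 0, 9)   # mid-lumen: every element > 5 um off the wall
  st <- make_state(rbind(c(0, 0, 3), mid), c("STEM", "ENTEROCYTE"),
                   config = mini)
  set.seed(47)
  st2 <- lifecycle_update(st, 0.1)
  expect_equal(nrow(st2$cells), 2)           # grace update
  st3 <- lifecycle_update(st2, 0.1)
  expect_equal(nrow(st3$cells), 1)           # removed on the second
})

test_that("Paneth identity is absorbing across lifecycle updates", {
  mini <- mini_config()
  st <- make_state(rbind(c(0, 0, 3), c(7, 0, 6), c(-7, 0, 6)),
                   c("STEM", "PANETH", "GOBLET"), config = mini)
  set.seed(48)
  for (i in 1:10) {
    st <- lifecycle_update(st, 0.5)
    expect_true(all(st$cells$type[st$cells$cell_id == 2] ==
                      CELL_TYPES["PANETH"]))
  }
})
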