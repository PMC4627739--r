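test_that("adsorption rate matches hand evaluation and degenerate cases", {
  g <- grid_1d(length = 3e-6, n_cells = 3)
  p <- adsorption_params(lambda = 1e-6, k_eff = 5e-7, variant = "full")
  ## hand evaluation with the backward-difference rule:
  ## 5e-7 * (1 - 0.5) * (0.5/1e-6 + 0.5/1e-6) = 0.25 1/s
  f <- concentration_field_1d(g, values = c(1, 0.5, 0))
  expect_equal(rhs_1d(f, p)[2], 0.25)
  ## saturated and empty fields have zero rate
  expect_equal(rhs_1d(concentration_field_1d(g, values = rep(1, 3)), p),
               rep(0, 3))
  expect_equal(rhs_1d(concentration_field_1d(g, values = rep(0, 3)), p),
               rep(0, 3))
  ## bet drops the volumetric term, rosen drops saturation too
  pb <- adsorption_params(lambda = 1e-6, k_eff = 5e-7, variant = "bet")
  expect_equal(rhs_1d(f, pb)[2], 5e-7 * 0.5 * 0.5 / 1e-6)
  pr <- adsorption_params(lambda = 1e-6, k_eff = 5e-7, variant = "rosen")
  expect_equal(rhs_1d(f, pr)[2], 5e-7 * 0.5 / 1e-6)
  f$values[2] <- NaN
  expect_error(rhs_1d(f, p), "non-finite")
})

test_that("explicit stepping respects the substrate, bounds and stability", {
  g <- grid_1d(length = 1e-5, n_cells = 10)
  p <- adsorption_params(lambda = 1e-6, k_eff = 5e-7)
  f <- concentration_field_1d(g)       # substrate seed
  expect_error(step_1d(f, p, dt = -1), "positive")
  expect_error(step_1d(f, p, dt = 100), "stability")
  dt <- stable_dt_1d(p, g)
  f1 <- step_1d(f, p, dt)
  ## only the node adjacent to the substrate changes after one step
  expect_gt(f1$values[2], 0)
  expect_equal(f1$values[c(1, 3:10)], f$values[c(1, 3:10)])
  expect_equal(f1$time, dt)
  ## saturated field is a fixed point
  fs <- concentration_field_1d(g, values = rep(1, 10))
  expect_equal(step_1d(fs, p, dt)$values, rep(1, 10))
})

test_that("the non-saturating variant obeys the exact discrete flux balance", {
  ## each step adds exactly k_eff * dt to the integral of C
  ## (telescoping upwind flux with boundary values 1 and 0)
  g <- grid_1d(length = 4e-5, n_cells = 40)
  p <- adsorption_params(lambda = 1e-6, k_eff = 5e-7, variant = "rosen")
  f <- concentration_field_1d(g)
  dt <- stable_dt_1d(p, g)
  n_steps <- 20L
  I0 <- sum(f$values) * g$dx
  for (i in seq_len(n_steps)) f <- step_1d(f, p, dt)
  expect_equal(sum(f$values) * g$dx - I0, p$k_eff * n_steps * dt,
               tolerance = 1e-12)
})

test_that("the non-saturating variant is pure advection at speed k_eff", {
  ## fine grid: a smooth profile is transported nearly rigidly
  g <- grid_1d(length = 4e-5, n_cells = 400)
  p <- adsorption_params(lambda = 1e-6, k_eff = 5e-7, variant = "rosen")
  x <- grid_1d_positions(g)
  v0 <- 1 / (1 + exp((x - 1e-5) / 1e-6))
  tr <- simulate_1d(concentration_field_1d(g, values = v0), p, t_end = 20,
                    record_every = 20)
  shifted <- approx(x + p$k_eff * 20, v0, x, rule = 2)$y
  expect_lt(max(abs(tr$values[nrow(tr$values), ] - shifted)), 0.05)
  ## and the plateau of the integral velocity equals k_eff to round-off
  tr2 <- simulate_1d(concentration_field_1d(g), p, t_end = 30)
  expect_equal(wave_velocity_1d(tr2)$plateau, p$k_eff, tolerance = 1e-9)
})

test_that("trajectories record snapshots and flag boundary contact", {
  g <- grid_1d(length = 2e-5, n_cells = 20)
  p <- adsorption_params()
  tr0 <- simulate_1d(concentration_field_1d(g), p, t_end = 0)
  expect_equal(nrow(tr0$values), 1L)
  tr <- simulate_1d(concentration_field_1d(g), p, t_end = 10, record_every = 2)
  expect_gte(max(tr$times), 10 - tr$dt)
  expect_false(is.unsorted(tr$times))
  ## long run on a short domain must flag the boundary
  trb <- simulate_1d(concentration_field_1d(g), p, t_end = 40)
  expect_true(trb$boundary_reached)
})

test_that("saturating variants stay bounded and non-decreasing in time", {
  g <- grid_1d(length = 3e-5, n_cells = 30)
  for (variant in c("full", "bet")) {
    for (seed in c(11L, 23L)) {
      p <- adsorption_params(lambda = 1.5e-6, k_eff = 5e-7, variant = variant)
      f <- concentration_field_1d(g, values = random_front_profile(30, seed))
      dt <- stable_dt_1d(p, g)
      for (s in 1:25) {
        f2 <- step_1d(f, p, dt)
        expect_true(all(f2$values >= f$values - 1e-15))
        expect_true(all(f2$values >= 0 & f2$values <= 1))
        f <- f2
      }
    }
  }
})

test_that("wave velocity requires history and is zero for a frozen field", {
  g <- grid_1d(length = 2e-5, n_cells = 20)
  p <- adsorption_params()
  tr <- simulate_1d(concentration_field_1d(g), p, t_end = 5, record_every = 5)
  expect_error(wave_velocity_1d(tr), "3 snapshots")
  frozen <- tr
  frozen$times <- c(0, 1, 2, 3)
  frozen$values <- matrix(rep(tr$values[1, ], 4), 4, byrow = TRUE)
  v <- wave_velocity_1d(frozen)
  expect_equal(v$velocity, c(0, 0))
  expect_equal(v$plateau, 0)
})

test_that("front position interpolates the first downcrossing", {
  g <- grid_1d(length = 4e-6, n_cells = 4)
  f <- concentration_field_1d(g, values = c(1, 1, 0, 0))
  expect_equal(front_position(f, level = 0.5), 1.5e-6)
  expect_error(front_position(concentration_field_1d(g, values = rep(0, 4))),
               "below")
  expect_error(front_position(concentration_field_1d(g, values = rep(1, 4))),
               "above")
})

test_that("front steepness: step and ramp geometry", {
  g <- grid_1d(length = 4e-6, n_cells = 4)
  st <- front_steepness(concentration_field_1d(g, values = c(1, 1, 0, 0)))
  expect_lte(st$width, g$dx)
  expect_equal(st$max_slope, 1 / g$dx)
  g2 <- grid_1d(length = 11e-6, n_cells = 11)
  ramp <- concentration_field_1d(g2, values = seq(1, 0, by = -0.1))
  st2 <- front_steepness(ramp)
  expect_equal(st2$width, 8 * g2$dx)
  expect_error(front_steepness(concentration_field_1d(
    g2, values = rep(0.5, 11))), "cross")
})

test_that("two independent velocity estimators agree on a converged run", {
  g <- grid_1d(length = 1e-4, n_cells = 100)
  p <- adsorption_params(lambda = 1e-6, k_eff = 5e-7, variant = "full")
  tr <- simulate_1d(concentration_field_1d(g), p, t_end = 60, record_every = 5)
  v_int <- wave_velocity_1d(tr)$plateau
  n <- length(tr$times)
  pos <- vapply(c(n - 3L, n), function(i) front_position(snapshot_1d(tr, i)), 0)
  v_pos <- diff(pos) / (tr$times[n] - tr$times[n - 3L])
  expect_lt(abs(v_pos - v_int) / v_int, 0.05)
})

test_that("front width scales with the particle size lambda", {
  ## the volumetric filling term C/lambda sets the profile width: larger
  ## particles fill the aggregate more slowly behind the front, giving
  ## wider (shallower) converged profiles
  g <- grid_1d(length = 2e-4, n_cells = 200)
  widths <- vapply(c(1e-6, 2e-6, 3e-6), function(lam) {
    p <- adsorption_params(lambda = lam, k_eff = 5e-7, variant = "full")
    tr <- simulate_1d(concentration_field_1d(g), p, t_end = 80,
                      record_every = 80)
    front_steepness(snapshot_1d(tr, -1L))$width
  }, 0)
  expect_true(all(diff(widths) > 0))
})

test_that("the full model approaches the single-site variant as lambda grows", {
  g <- grid_1d(length = 1e-4, n_cells = 100)
  dt <- 0.5 * g$dx / (5e-7 * (1 + g$dx / 1e-5))
  run <- function(variant, lam) {
    p <- adsorption_params(lambda = lam, k_eff = 5e-7, variant = variant)
    tr <- simulate_1d(concentration_field_1d(g), p, t_end = 60, dt = dt,
                      record_every = 60)
    tr$values[nrow(tr$values), ]
  }
  ref <- run("bet", 1e-3)
  gaps <- vapply(c(1e-5, 1e-4, 1e-3), function(lam)
    max(abs(run("full", lam) - ref)), 0)
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 0.01)
})
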