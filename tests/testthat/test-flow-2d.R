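test_that("analytic Poiseuille matches the closed forms", {
  fl <- fluid_params(); g <- channel_grid()
  pa <- poiseuille_analytic(fl, g, delta_p = 30)
  ## u_max = dp M^2 / (8 rho nu L); discrete maximum sits half a cell off
  ## the centerline, hence the tolerance
  expect_equal(max(pa$u), 30 * (5e-5)^2 / (8 * 1060 * 5e-6 * 15e-5),
               tolerance = 5e-4)
  ## wall shear rate dp M / (2 rho nu L) ~ 943 1/s, about the 1000 1/s the
  ## velocity-profile variant uses (the two BCs are nearly equivalent);
  ## the one-sided estimate on the parabola carries a dy/(2M) bias
  expect_equal(wall_shear_rate(pa, g), 30 * 5e-5 / (2 * 1060 * 5e-6 * 15e-5),
               tolerance = 0.011)
  expect_equal(max(abs(poiseuille_analytic(fl, g, 0)$u)), 0)
  expect_equal(max(abs(pa$v)), 0)
})

test_that("discrete divergence: analytic cases", {
  fl <- fluid_params(); g <- small_grid()
  pa <- poiseuille_analytic(fl, g, delta_p = 30)
  expect_lt(max(abs(divergence(pa))), 1e-12)
  ## u = a x has divergence a everywhere
  a <- 3.5
  xf <- (0:g$nx) * g$dx
  ulin <- matrix(rep(a * xf, g$ny), g$nx + 1L, g$ny)
  flx <- flow_field(g, u = ulin)
  expect_equal(divergence(flx), matrix(a, g$nx, g$ny))
})

test_that("shear-rate field: uniform flow, Poiseuille and rigid block", {
  fl <- fluid_params(); g <- channel_grid()
  ## uniform flow has no velocity gradients away from the walls; use the
  ## dudy mode on an interior-uniform field
  pa <- poiseuille_analytic(fl, g, delta_p = 30)
  gam <- shear_rate_field(pa, g)
  gw <- 30 * 5e-5 / (2 * 1060 * 5e-6 * 15e-5)
  ## wall-adjacent cells: ~ gw * (1 - dy/M), within the first-order ghost
  expect_equal(mean(gam[, 1]), gw * (1 - g$dy / g$height), tolerance = 0.01)
  expect_lt(mean(gam[, 25]), 0.03 * gw)          # near-zero at centerline
  expect_equal(shear_rate_field(flow_field(g), g), matrix(0, g$nx, g$ny))
  ## dudy mode agrees with the strain mode for unidirectional flow
  expect_equal(shear_rate_field(pa, g, mode = "dudy"), gam, tolerance = 1e-10)
})

test_that("steady Stokes solve recovers plane Poiseuille within 1%", {
  fl <- fluid_params(); g <- channel_grid(); bc <- flow_bc("pressure_gradient", 30)
  sol <- acceptance_run("stokes_poiseuille", function()
    solve_steady_flow(fl, g, bc, mode = "stokes"))
  pa <- poiseuille_analytic(fl, g, 30)
  expect_lt(max(abs(sol$u - pa$u)) / max(pa$u), 0.01)
  expect_lt(max(abs(sol$v)) / max(pa$u), 1e-6)
  expect_lt(thrombosim:::scaled_divergence(sol, g), 1e-10)
  ## boundary pressure data carried with the field
  expect_equal(attr(sol$p, "p_in") - attr(sol$p, "p_out"), 30)
})

test_that("velocity-profile inlet carries the prescribed parabola", {
  fl <- fluid_params(); g <- channel_grid()
  bc <- flow_bc("velocity_profile", wall_shear = 1000)
  f0 <- apply_flow_bcs(flow_field(g), bc, g)
  ## peak gw * M / 4, wall slope gw
  expect_equal(max(f0$u[1, ]), 1000 * 5e-5 / 4, tolerance = 1e-3)
  expect_equal(f0$u[1, 1] / (g$dy / 2), 1000, tolerance = 0.02)
  sol <- solve_steady_flow(fl, g, bc, mode = "stokes")
  expect_equal(max(sol$u[1, ]), 1000 * 5e-5 / 4, tolerance = 1e-3)
  expect_lt(thrombosim:::scaled_divergence(sol, g), 1e-10)
})

test_that("masked faces and walls carry exactly zero velocity", {
  fl <- fluid_params(); g <- small_grid(); bc <- flow_bc("pressure_gradient", 30)
  mask <- matrix(FALSE, g$nx, g$ny); mask[13:17, 1:4] <- TRUE
  f <- apply_flow_bcs(poiseuille_analytic(fl, g, 30), bc, g, mask)
  expect_equal(max(abs(f$u[13:18, 1:4])), 0)
  expect_equal(max(abs(f$v[13:17, 1:5])), 0)
  expect_equal(max(abs(f$v[, c(1, g$ny + 1L)])), 0)
  sol <- solve_steady_flow(fl, g, bc, mask, mode = "stokes")
  expect_equal(max(abs(sol$u[13:18, 1:4])), 0)
  expect_equal(max(abs(sol$v[13:17, 1:5])), 0)
})

test_that("full-height slab blocks the channel; a bump accelerates the gap", {
  fl <- fluid_params(); g <- small_grid(); bc <- flow_bc("pressure_gradient", 30)
  slab <- matrix(FALSE, g$nx, g$ny); slab[14:16, ] <- TRUE
  fs <- solve_steady_flow(fl, g, bc, slab, mode = "stokes")
  expect_lt(max(abs(fs$u[18:31, ])), 1e-12)
  ## the full pressure drop concentrates across the slab
  expect_equal(mean(fs$p[13, ] - fs$p[17, ]), 30, tolerance = 1e-6)
  ## mass conservation through a narrowed gap: with the fixed-flux
  ## (velocity-profile) inlet the peak above a half-height bump must
  ## exceed the unobstructed centerline speed
  bcv <- flow_bc("velocity_profile", wall_shear = 1000)
  bump <- matrix(FALSE, g$nx, g$ny); bump[14:16, 1:5] <- TRUE
  fb <- solve_steady_flow(fl, g, bcv, bump, mode = "stokes")
  free <- solve_steady_flow(fl, g, bcv, mode = "stokes")
  expect_gt(max(abs(fb$u[14:17, 6:g$ny])), max(abs(free$u)))
})

test_that("one projection step: divergence contract and fixed point", {
  fl <- fluid_params(); g <- small_grid(); bc <- flow_bc("pressure_gradient", 30)
  mask <- matrix(FALSE, g$nx, g$ny); mask[13:17, 1:4] <- TRUE
  cache <- make_flow_cache(g, bc, mask)
  f <- apply_flow_bcs(flow_field(g), bc, g, mask)
  dt <- stable_dt_flow(fl, g, 0)
  f1 <- chorin_step(f, fl, dt, bc, g, mask, cache)
  expect_lt(thrombosim:::scaled_divergence(f1, g, mask), 1e-8)
  expect_equal(max(abs(f1$u[13:18, 1:4])), 0)
  expect_error(chorin_step(f, fl, dt = 1, bc, g, mask, cache), "stability")
  ## the discrete steady state is a fixed point (advection vanishes for
  ## unidirectional flow)
  c0 <- make_flow_cache(g, bc, NULL)
  fs <- solve_steady_flow(fl, g, bc, mode = "stokes")
  f2 <- chorin_step(fs, fl, stable_dt_flow(fl, g, max(abs(fs$u))), bc, g,
                    NULL, c0)
  expect_lt(max(abs(f2$u - fs$u)) / max(fs$u), 1e-10)
  ## zero flow under zero forcing remains zero
  bc0 <- flow_bc("pressure_gradient", delta_p = 0)
  cz <- make_flow_cache(g, bc0, NULL)
  fz <- chorin_step(flow_field(g), fl, dt, bc0, g, NULL, cz)
  expect_equal(max(abs(fz$u), abs(fz$v)), 0)
})

test_that("time-marched and direct steady solves agree", {
  fl <- fluid_params(); bc <- flow_bc("pressure_gradient", 30)
  g <- small_grid(nx = 30L, ny = 15L)
  mask <- matrix(FALSE, g$nx, g$ny); mask[13:17, 1:7] <- TRUE
  fm <- solve_steady_flow(fl, g, bc, mask, mode = "march", tol = 1e-6)
  fs <- solve_steady_flow(fl, g, bc, mask, mode = "stokes")
  expect_lt(abs(max(abs(fm$u)) - max(abs(fs$u))) / max(abs(fs$u)), 0.02)
  expect_error(solve_steady_flow(fl, g, bc, mask, mode = "march",
                                 tol = 1e-12, max_iter = 100L), "converge")
})

test_that("symmetric mask gives symmetric u and antisymmetric v", {
  fl <- fluid_params(); bc <- flow_bc("pressure_gradient", 30)
  g <- channel_grid(length = 6e-5, height = 3.2e-5, nx = 30L, ny = 16L)
  mask <- matrix(FALSE, 30, 16); mask[14:16, 7:10] <- TRUE
  f <- solve_steady_flow(fl, g, bc, mask, mode = "stokes")
  expect_lt(max(abs(f$u - f$u[, 16:1])) / max(abs(f$u)), 1e-10)
  expect_lt(max(abs(f$v + f$v[, 17:1])) / max(abs(f$u)), 1e-10)
})
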