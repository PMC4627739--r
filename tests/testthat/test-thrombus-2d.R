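test_that("injury initial condition selects wall cells by center", {
  g <- channel_grid()
  C <- init_injury(g, injury_spec())          # 15 um centered injury
  expect_equal(sum(C > 0), 15L)
  expect_true(all(C[C > 0] == 1))
  expect_true(all(which(C == 1, arr.ind = TRUE)[, 2] == 1L))
  expect_equal(sum(init_injury(g, injury_spec(l0 = 1e-6)) > 0), 1L)
  expect_equal(sum(init_injury(g, injury_spec(l0 = 150e-6, center = 75e-6)) > 0),
               150L)
  expect_error(init_injury(g, injury_spec(l0 = 15e-6, center = 1e-6)),
               "outside")
})

test_that("concentration BCs: ghost ring values and idempotence", {
  C <- matrix(0.3, 4, 3)
  Cp <- apply_concentration_bcs(C)
  expect_equal(dim(Cp), c(6L, 5L))
  expect_equal(Cp[1, 2:4], rep(0, 3))         # inlet A Dirichlet 0
  expect_equal(Cp[6, 2:4], rep(0.3, 3))       # outlet B zero-gradient
  expect_equal(Cp[2:5, 1], rep(0.3, 4))       # wall D zero-gradient
  expect_equal(Cp[2:5, 5], rep(0.3, 4))       # wall C zero-gradient
  expect_identical(apply_concentration_bcs(Cp), Cp)
  Z <- apply_concentration_bcs(matrix(0, 4, 3))
  expect_equal(max(abs(Z)), 0)
})

test_that("2D rate: hand-evaluated stencil and degenerate cases", {
  g <- channel_grid(length = 3e-6, height = 3e-6, nx = 3, ny = 3)
  pars <- thrombus_params()
  C <- matrix(0, 3, 3); C[2, 2] <- 0.5
  fl <- flow_field(g, u = matrix(0.01, 4, 3))  # uniform rightward flow
  gam <- matrix(1000, 3, 3)
  r <- concentration_rhs_2d(C, fl, gam, pars, g)
  ## center cell: adhesion (no uphill neighbor) minus convective outflux
  adh <- 8e-11 * 1000 * 0.5 * (0.5 / 3e-6)
  conv <- 7e-5 * 0.01 * 0.5 / 1e-6
  expect_equal(r[2, 2], adh - conv)
  ## downstream cell: uphill gradient 0.5/dx plus convective influx
  expect_equal(r[3, 2], 8e-11 * 1000 * (0.5 / 1e-6) + 7e-5 * 0.01 * 0.5 / 1e-6)
  ## still fluid: both terms carry a flow factor
  expect_equal(concentration_rhs_2d(C, flow_field(g), matrix(0, 3, 3), pars, g),
               matrix(0, 3, 3))
  ## saturated field with divergence-free flow: zero rate away from the
  ## inlet (the Dirichlet C = 0 inlet flushes the first column)
  g5 <- channel_grid(length = 5e-6, height = 3e-6, nx = 5, ny = 3)
  pa <- poiseuille_analytic(fluid_params(), g5, 30)
  gam2 <- shear_rate_field(pa, g5)
  rs <- concentration_rhs_2d(matrix(1, 5, 3), pa, gam2, pars, g5)
  expect_equal(max(abs(rs[2:5, ])), 0)
  expect_lt(rs[1, 2], 0)
  expect_error(concentration_rhs_2d(matrix(0, 2, 2), fl, gam, pars, g),
               "grid")
})

test_that("threshold masking is inclusive and reports changes", {
  m <- update_mask(matrix(c(0.89, 0.9, 0.91, 0.2), 2, 2), c_b = 0.9)
  expect_equal(as.vector(m), c(FALSE, TRUE, TRUE, FALSE))
  m2 <- update_mask(matrix(c(0.89, 0.9, 0.91, 0.95), 2, 2), 0.9, prev = m)
  expect_true(attr(m2, "changed"))
  m3 <- update_mask(matrix(c(0.89, 0.9, 0.91, 0.2), 2, 2), 0.9, prev = m)
  expect_false(attr(m3, "changed"))
})

test_that("still fluid freezes the injury (zero-flow consistency)", {
  g <- small_grid(nx = 20L, ny = 8L)
  sim <- simulate_coupled(g, fluid_params(),
                          flow_bc("pressure_gradient", delta_p = 0),
                          thrombus_params(), injury_spec(l0 = 5e-6, center = 10e-6),
                          t_end = 50, record_every = 25)
  C0 <- sim$conc[[1]]
  Cf <- sim$conc[[length(sim$conc)]]
  expect_equal(Cf, C0)
  expect_equal(max(abs(sim$flow$u), abs(sim$flow$v)), 0)
})

test_that("coupled growth keeps bounds, monotone mask and torch bias", {
  g <- small_grid(nx = 40L, ny = 12L)
  sim <- acceptance_run("small_coupled", function()
    simulate_coupled(g, fluid_params(), flow_bc("pressure_gradient", 30),
                     thrombus_params(), injury_spec(l0 = 6e-6, center = 16e-6),
                     t_end = 400, record_every = 40))
  masks <- lapply(sim$conc, function(C) C >= sim$params$c_b)
  for (k in seq_along(masks)) {
    expect_true(all(sim$conc[[k]] >= 0 & sim$conc[[k]] <= 1))
    if (k > 1) expect_true(all(masks[[k]] >= masks[[k - 1]]))  # never shrinks
  }
  expect_gt(sum(masks[[length(masks)]]), sum(masks[[1]]))
  ## fluid just outside the thrombus is slow and speeds up as C decreases
  Cf <- sim$conc[[length(sim$conc)]]
  uc <- 0.5 * (sim$flow$u[1:g$nx, ] + sim$flow$u[2:(g$nx + 1L), ])
  vc <- 0.5 * (sim$flow$v[, 1:g$ny] + sim$flow$v[, 2:(g$ny + 1L)])
  speed <- sqrt(uc^2 + vc^2)
  ## the fluid permeating the dense sub-threshold shell is slower than the
  ## flow over dilute regions, and small relative to the unobstructed
  ## centerline speed
  dense <- mean(speed[Cf >= 0.6 & Cf < 0.9])
  dilute <- mean(speed[Cf < 0.3])
  expect_lt(dense, dilute)
  u_free <- max(poiseuille_analytic(sim$fluid, g, sim$bc$delta_p)$u)
  expect_lt(dense, 0.3 * u_free)
})

test_that("refresh cadence bounds the lag between mask and flow", {
  g <- small_grid(nx = 20L, ny = 8L)
  sim <- simulate_coupled(g, fluid_params(), flow_bc("pressure_gradient", 30),
                          thrombus_params(), injury_spec(l0 = 5e-6, center = 10e-6),
                          t_end = 60, record_every = 30, refresh_every = 5L)
  ## at least one refresh per 5 steps must have happened
  expect_gte(sim$refreshes, sim$steps %/% 5L)
  ## final flow honors the final mask exactly
  fx <- thrombosim:::face_fixes(g, sim$bc, sim$mask)
  expect_equal(max(abs(sim$flow$u[fx$ufix])), 0)
})
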