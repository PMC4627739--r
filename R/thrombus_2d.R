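## 2D thrombus growth: shear-dependent adhesion-convection equation for the
## platelet concentration, its boundary conditions, the concentration-
## threshold obstacle rule, and the coupled quasi-steady growth driver.

#' Injury initial condition
#'
#' Sets concentration 1 on the wall-adjacent row of cells (bottom wall D)
#' whose centers fall in the half-open segment
#' `[center - l0/2, center + l0/2)`; zero elsewhere.
#'
#' @param grid [channel_grid()].
#' @param injury [injury_spec()].
#' @return `nx x ny` concentration matrix.
#' @export
init_injury <- function(grid, injury) {
  stopifnot(inherits(grid, "channel_grid"), inherits(injury, "injury_spec"))
  ctr <- injury_center(injury, grid)
  a <- ctr - injury$l0 / 2
  b <- ctr + injury$l0 / 2
  tol <- 1e-9 * grid$length
  if (a < -tol || b > grid$length + tol)
    stop("injury extends outside the bottom wall", call. = FALSE)
  xc <- (seq_len(grid$nx) - 0.5) * grid$dx
  C <- matrix(0, grid$nx, grid$ny)
  C[xc >= a - tol & xc < b - tol, 1L] <- 1
  C
}

#' Apply the concentration boundary conditions
#'
#' Dirichlet zero at the inlet A (clean inflowing blood), zero-gradient at
#' the outlet B and at both walls, realized by a ghost-cell ring: the
#' returned matrix is `(nx+2) x (ny+2)` with attribute `ghost = TRUE`.
#' Passing an already ghost-padded field refreshes the ring (the operation
#' is idempotent).  The injury is initial data, not a boundary condition:
#' injured cells evolve freely afterwards.
#'
#' @param C `nx x ny` interior concentration matrix, or a ghost-padded
#'   matrix produced by this function.
#' @return Ghost-padded `(nx+2) x (ny+2)` matrix.
#' @export
apply_concentration_bcs <- function(C) {
  if (isTRUE(attr(C, "ghost"))) C <- C[2:(nrow(C) - 1L), 2:(ncol(C) - 1L)]
  nx <- nrow(C); ny <- ncol(C)
  Cp <- matrix(0, nx + 2L, ny + 2L)
  Cp[2:(nx + 1L), 2:(ny + 1L)] <- C
  Cp[1L, ] <- 0                                  # inlet A: C = 0
  Cp[nx + 2L, 2:(ny + 1L)] <- C[nx, ]            # outlet B: dC/dx = 0
  Cp[2:(nx + 1L), 1L] <- C[, 1L]                 # wall D: dC/dy = 0
  Cp[2:(nx + 1L), ny + 2L] <- C[, ny]            # wall C: dC/dy = 0
  attr(Cp, "ghost") <- TRUE
  Cp
}

interior_conc <- function(Cp) {
  if (!isTRUE(attr(Cp, "ghost"))) return(Cp)
  Cp[2:(nrow(Cp) - 1L), 2:(ncol(Cp) - 1L)]
}

#' Right-hand side of the 2D concentration equation
#'
#' `dC/dt = k_adh * gamma * (1 - C/c_max) * (C/lambda + |grad C|)
#'  - k_rol * div(v C)`.
#' The gradient magnitude uses the Godunov (Rouy-Tourin) upwind stencil,
#' the 2D extension of the substrate-side 1D difference: per axis the
#' largest uphill one-sided difference.  The convective term uses
#' conservative upwind face fluxes of `v C`; since every face of a masked
#' cell carries zero velocity, convection vanishes identically inside the
#' thrombus and acts only at its boundary.
#'
#' @param C `nx x ny` interior concentration matrix.
#' @param flow A `flow_field` consistent with the current mask.
#' @param gamma `nx x ny` shear-rate field, 1/s (see [shear_rate_field()]).
#' @param params [thrombus_params()].
#' @param grid [channel_grid()].
#' @return `nx x ny` matrix of rates, 1/s.
#' @export
concentration_rhs_2d <- function(C, flow, gamma, params, grid) {
  stopifnot(inherits(params, "thrombus_params"), inherits(grid, "channel_grid"))
  nx <- grid$nx; ny <- grid$ny
  if (!all(dim(C) == c(nx, ny))) stop("C does not match the grid", call. = FALSE)
  if (!all(dim(gamma) == c(nx, ny))) stop("gamma does not match the grid",
                                          call. = FALSE)
  if (!all(dim(flow$u) == c(nx + 1L, ny)) || !all(dim(flow$v) == c(nx, ny + 1L)))
    stop("flow does not match the grid", call. = FALSE)
  dx <- grid$dx; dy <- grid$dy
  Cp <- apply_concentration_bcs(C)
  ic <- 2:(nx + 1L); jc <- 2:(ny + 1L)
  CW <- Cp[ic - 1L, jc]; CE <- Cp[ic + 1L, jc]
  CS <- Cp[ic, jc - 1L]; CN <- Cp[ic, jc + 1L]
  gx <- pmax(CW - C, CE - C, 0) / dx
  gy <- pmax(CS - C, CN - C, 0) / dy
  gradmag <- sqrt(gx^2 + gy^2)
  adhesion <- params$k_adh * gamma * (1 - C / params$c_max) *
    (C / params$lambda + gradmag)
  ## conservative upwind fluxes of v C on faces
  u <- flow$u; v <- flow$v
  CL <- Cp[1:(nx + 1L), jc]                   # left cell of each u face
  CR <- Cp[2:(nx + 2L), jc]
  Fx <- u * ifelse(u >= 0, CL, CR)
  CB <- Cp[ic, 1:(ny + 1L)]
  CT <- Cp[ic, 2:(ny + 2L)]
  Fy <- v * ifelse(v >= 0, CB, CT)
  divF <- (Fx[2:(nx + 1L), , drop = FALSE] - Fx[1:nx, , drop = FALSE]) / dx +
    (Fy[, 2:(ny + 1L), drop = FALSE] - Fy[, 1:ny, drop = FALSE]) / dy
  adhesion - params$k_rol * divF
}

#' Obstacle mask from the concentration field
#'
#' A cell belongs to the rigid thrombus once its concentration reaches the
#' threshold: `mask = (C >= c_b)` (inclusive).  The result carries the
#' attribute `changed` comparing against `prev`, used to trigger
#' quasi-steady flow refreshes.
#'
#' @param C Interior concentration matrix (ghost-padded input accepted).
#' @param c_b Threshold concentration.
#' @param prev Previous mask for change detection, or NULL.
#' @return Logical matrix with attribute `changed`.
#' @export
update_mask <- function(C, c_b, prev = NULL) {
  C <- interior_conc(C)
  mask <- C >= c_b
  attr(mask, "changed") <- if (is.null(prev)) TRUE else !identical(
    as.vector(mask), as.vector(prev))
  mask
}

#' Explicit stability bound for the 2D concentration update
#'
#' `dt <= safety * min(h / (k_adh gamma_max (1 + h/lambda)),
#'                     h / (k_rol vmax))` with `h = min(dx, dy)`.
#'
#' @param params [thrombus_params()].
#' @param grid [channel_grid()].
#' @param gamma_max Maximum shear rate, 1/s.
#' @param vmax Maximum face speed, m/s.
#' @param safety Safety factor (default 0.5).
#' @return Maximum stable time step, s (Inf in still fluid).
#' @export
stable_dt_2d <- function(params, grid, gamma_max, vmax, safety = 0.5) {
  h <- min(grid$dx, grid$dy)
  b1 <- if (gamma_max > 0)
    h / (params$k_adh * gamma_max * (1 + h / params$lambda)) else Inf
  b2 <- if (params$k_rol > 0 && vmax > 0) h / (params$k_rol * vmax) else Inf
  safety * min(b1, b2)
}

#' Coupled thrombus-growth simulation
#'
#' Integrates the 2D concentration equation coupled to the channel flow.
#' Each step: (1) the steady flow is refreshed if the obstacle mask changed
#' since the last refresh, or at the latest every `refresh_every`
#' concentration steps (quasi-steady coupling: the flow relaxes in
#' milliseconds while growth takes seconds); (2) the shear-rate field is
#' evaluated; (3) the concentration is advanced by explicit Euler with its
#' boundary conditions and clipped to `[0, c_max]`; (4) the mask is
#' updated from the threshold rule.
#'
#' @param grid [channel_grid()].
#' @param fluid [fluid_params()].
#' @param bc [flow_bc()].
#' @param params [thrombus_params()].
#' @param injury [injury_spec()].
#' @param t_end Final time, s.
#' @param dt Time step, s, or NULL for the stability-bound automatic step
#'   (recomputed at every flow refresh).
#' @param record_every Snapshot cadence, s (default `t_end / 20`).
#' @param flow_mode `"stokes"` (direct steady solve, default) or
#'   `"march"` (pseudo-time Chorin marching).
#' @param refresh_every Maximum number of concentration steps between flow
#'   refreshes (default 100).
#' @param shear_mode Shear-rate definition, `"strain"` or `"dudy"`.
#' @param store_flow If TRUE, keep the flow field at every snapshot.
#' @param verbose Print refresh diagnostics.
#' @return An object of class `thrombus_sim`: `times` (s), `conc` (list of
#'   `nx x ny` snapshots), final `flow`, `gamma` and `mask`, the
#'   configuration objects, `refreshes` and `steps` counters, an
#'   `outlet_reached` flag set when the thrombus touches the outlet column
#'   (shape metrics become boundary-limited from then on), and an
#'   `occluded` flag if a velocity-profile run had to halt because the
#'   thrombus sealed the cross-section (with a warning).
#' @export
simulate_coupled <- function(grid, fluid, bc, params, injury, t_end,
                             dt = NULL, record_every = NULL,
                             flow_mode = c("stokes", "march"),
                             refresh_every = 100L,
                             shear_mode = c("strain", "dudy"),
                             store_flow = FALSE, verbose = FALSE) {
  flow_mode <- match.arg(flow_mode)
  shear_mode <- match.arg(shear_mode)
  stopifnot(inherits(grid, "channel_grid"), inherits(fluid, "fluid_params"),
            inherits(bc, "flow_bc"), inherits(params, "thrombus_params"),
            inherits(injury, "injury_spec"))
  check_positive(t_end, "t_end")
  if (is.null(record_every)) record_every <- t_end / 20
  C <- init_injury(grid, injury)
  mask <- update_mask(C, params$c_b)
  solve_flow <- function(mask, init) {
    if (flow_mode == "stokes")
      solve_steady_flow(fluid, grid, bc, mask, mode = "stokes")
    else
      solve_steady_flow(fluid, grid, bc, mask, mode = "march", init = init)
  }
  flow <- solve_flow(mask, NULL)
  gamma <- shear_rate_field(flow, grid, mode = shear_mode)
  refreshes <- 1L
  steps_since <- 0L
  mask_dirty <- FALSE
  auto_dt <- is.null(dt)
  pick_dt <- function() {
    if (!auto_dt) return(dt)
    d <- stable_dt_2d(params, grid, max(gamma), max(abs(flow$u), abs(flow$v)))
    if (!is.finite(d)) d <- record_every
    min(d, record_every)
  }
  dt_cur <- pick_dt()
  times <- 0
  conc <- list(C)
  flows <- if (store_flow) list(flow) else NULL
  t <- 0
  next_rec <- record_every
  steps <- 0L
  outlet_reached <- any(mask[grid$nx, ])
  occluded <- FALSE
  while (t < t_end - 1e-9 * t_end) {
    if (mask_dirty || steps_since >= refresh_every) {
      if (bc$variant == "velocity_profile" && !channel_open(mask)) {
        ## full occlusion: prescribed inflow has no incompressible solution
        warning(sprintf(
          "thrombus occluded the channel at t = %.3g s; run halted early", t),
          call. = FALSE)
        occluded <- TRUE
        break
      }
      flow <- solve_flow(mask, flow)
      gamma <- shear_rate_field(flow, grid, mode = shear_mode)
      refreshes <- refreshes + 1L
      steps_since <- 0L
      mask_dirty <- FALSE
      dt_cur <- pick_dt()
      if (verbose)
        message(sprintf("t = %.3g s: flow refresh #%d (%d masked cells)",
                        t, refreshes, sum(mask)))
    }
    step_dt <- min(dt_cur, t_end - t)
    rate <- concentration_rhs_2d(C, flow, gamma, params, grid)
    C <- pmin(pmax(C + step_dt * rate, 0), params$c_max)
    t <- t + step_dt
    steps <- steps + 1L
    steps_since <- steps_since + 1L
    newmask <- update_mask(C, params$c_b, prev = mask)
    if (attr(newmask, "changed")) mask_dirty <- TRUE
    mask <- newmask
    if (!outlet_reached && any(mask[grid$nx, ])) outlet_reached <- TRUE
    if (t >= next_rec - 1e-9 * t_end || t >= t_end - 1e-9 * t_end) {
      times <- c(times, t)
      conc[[length(conc) + 1L]] <- C
      if (store_flow) flows[[length(flows) + 1L]] <- flow
      next_rec <- next_rec + record_every
    }
  }
  if (occluded && times[length(times)] < t) {
    times <- c(times, t)
    conc[[length(conc) + 1L]] <- C
    if (store_flow) flows[[length(flows) + 1L]] <- flow
  }
  out <- list(times = times, conc = conc, flow = flow, gamma = gamma,
              mask = mask, grid = grid, fluid = fluid, bc = bc,
              params = params, injury = injury,
              refreshes = refreshes, steps = steps,
              outlet_reached = outlet_reached, occluded = occluded,
              flows = flows)
  class(out) <- "thrombus_sim"
  out
}
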