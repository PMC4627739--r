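## 1D spatial adsorption equation: right-hand side, explicit stepping and
## traveling-front diagnostics.

## Backward one-sided difference (substrate side); first node gets 0.
## This is the Godunov-type upwind choice for the gradient-magnitude term:
## information propagates from the high-concentration (aggregate) side.
backward_diff_1d <- function(values, dx) {
  c(0, diff(values)) / dx
}

#' Right-hand side of the 1D adsorption equation
#'
#' Evaluates the attachment rate per node for the selected model variant.
#' The spatial gradient uses the backward (substrate-side) one-sided
#' difference; the first node, which is the Dirichlet substrate, gets a
#' zero gradient.
#'
#' @param field A [concentration_field_1d()] object.
#' @param params An [adsorption_params()] object.
#' @return Numeric vector of rates, 1/s per node.
#' @examples
#' g <- grid_1d(length = 3e-6, n_cells = 3)
#' f <- concentration_field_1d(g, values = c(1, 0.5, 0))
#' rhs_1d(f, adsorption_params(lambda = 1e-6, k_eff = 5e-7))[2]  # 0.25 1/s
#' @export
rhs_1d <- function(field, params) {
  stopifnot(inherits(field, "conc_field_1d"),
            inherits(params, "adsorption_params"))
  v <- field$values
  if (any(!is.finite(v))) stop("non-finite concentration values", call. = FALSE)
  g <- backward_diff_1d(v, field$grid$dx)
  sat <- 1 - v / params$c_max
  switch(params$variant,
    full = params$k_eff * sat * (v / params$lambda + abs(g)),
    bet = params$k_eff * sat * abs(g),
    rosen = -params$k_eff * g,
    stop("unknown variant", call. = FALSE)
  )
}

#' Advance the 1D field by one explicit Euler step
#'
#' The leftmost node is a Dirichlet substrate and is held fixed.  The
#' updated field is clipped to `[0, c_max]` (forward Euler can overshoot
#' by O(dt^2)); for the `full` and `bet` variants the update is
#' non-decreasing at every interior node.
#'
#' @inheritParams rhs_1d
#' @param dt Time step, s; must satisfy [stable_dt_1d()].
#' @return The advanced [concentration_field_1d()].
#' @export
step_1d <- function(field, params, dt) {
  stopifnot(inherits(field, "conc_field_1d"))
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt <= 0)
    stop("dt must be a single positive number", call. = FALSE)
  dt_max <- stable_dt_1d(params, field$grid, safety = 1)
  if (dt > dt_max * (1 + 1e-12))
    stop(sprintf("dt = %g exceeds the stability bound %g s", dt, dt_max),
         call. = FALSE)
  r <- rhs_1d(field, params)
  v <- field$values + dt * r
  v[1L] <- field$values[1L]                     # Dirichlet substrate
  v <- pmin(pmax(v, 0), params$c_max)
  field$values <- v
  field$time <- field$time + dt
  field
}

#' Simulate the 1D adsorption equation
#'
#' Explicit finite-difference integration on a uniform grid, recording
#' snapshots at a fixed cadence.  With the default substrate seed the
#' solution develops a front that propagates in +x and, for the `full`
#' variant, converges to a traveling wave (late-time profiles are
#' translates of one another).
#'
#' @param initial Initial [concentration_field_1d()].
#' @param params [adsorption_params()].
#' @param t_end Final time, s (> 0, or 0 for just the initial field).
#' @param dt Time step, s; default is the stability bound with safety 0.5.
#' @param record_every Snapshot cadence, s; snapped to the nearest whole
#'   number of steps.  Default records ~50 snapshots.
#' @return An object of class `wave_1d`: list with `times` (s), `values`
#'   (snapshot-by-node matrix), `grid`, `params`, `dt`, and
#'   `boundary_reached` (TRUE once the front comes within 10 nodes of the
#'   right boundary, after which velocity measurements are unreliable).
#' @examples
#' g <- grid_1d(length = 4e-5, n_cells = 40)
#' traj <- simulate_1d(concentration_field_1d(g), adsorption_params(), t_end = 20)
#' @export
simulate_1d <- function(initial, params, t_end, dt = NULL, record_every = NULL) {
  stopifnot(inherits(initial, "conc_field_1d"),
            inherits(params, "adsorption_params"))
  if (!is.numeric(t_end) || length(t_end) != 1L || is.na(t_end) || t_end < 0)
    stop("t_end must be a single non-negative number", call. = FALSE)
  if (is.null(dt)) dt <- stable_dt_1d(params, initial$grid)
  if (t_end == 0) {
    out <- list(times = initial$time, values = matrix(initial$values, nrow = 1),
                grid = initial$grid, params = params, dt = dt,
                boundary_reached = FALSE)
    class(out) <- "wave_1d"
    return(out)
  }
  n_steps <- max(1L, ceiling(t_end / dt - 1e-9))
  if (is.null(record_every)) record_every <- t_end / 50
  rec_steps <- max(1L, as.integer(round(record_every / dt)))
  n <- initial$grid$n
  keep <- c(0L, seq(rec_steps, n_steps, by = rec_steps))
  if (keep[length(keep)] != n_steps) keep <- c(keep, n_steps)
  values <- matrix(NA_real_, length(keep), n)
  times <- numeric(length(keep))
  field <- initial
  values[1L, ] <- field$values
  times[1L] <- field$time
  k <- 2L
  boundary_reached <- FALSE
  guard <- max(1L, n - 10L)
  for (s in seq_len(n_steps)) {
    field <- step_1d(field, params, dt)
    if (!boundary_reached && field$values[guard] > 0.5 * params$c_max)
      boundary_reached <- TRUE
    if (k <= length(keep) && s == keep[k]) {
      values[k, ] <- field$values
      times[k] <- field$time
      k <- k + 1L
    }
  }
  out <- list(times = times, values = values, grid = initial$grid,
              params = params, dt = dt, boundary_reached = boundary_reached)
  class(out) <- "wave_1d"
  out
}

## Interior-snapshot velocities by central differencing of I(t) = int C dx.
integral_velocity <- function(times, integrals) {
  k <- length(times)
  idx <- 2:(k - 1)
  (integrals[idx + 1L] - integrals[idx - 1L]) / (times[idx + 1L] - times[idx - 1L])
}

#' Front propagation velocity of a 1D trajectory
#'
#' The velocity is the time derivative of the spatial integral of the
#' concentration, `V = d/dt int_0^L C dx`, computed by central differences
#' over the recorded snapshots.  The plateau value is the mean over the
#' last third of the series, after discarding snapshots where the front is
#' within 10 nodes of the right boundary.
#'
#' @param trajectory A `wave_1d` object with at least 3 snapshots.
#' @return An object of class `wave_velocity`: list with `times` (interior
#'   snapshot times, s), `velocity` (m/s) and `plateau` (m/s).
#' @export
wave_velocity_1d <- function(trajectory) {
  stopifnot(inherits(trajectory, "wave_1d"))
  k <- length(trajectory$times)
  if (k < 3L) stop("need at least 3 snapshots", call. = FALSE)
  dx <- trajectory$grid$dx
  I <- rowSums(trajectory$values) * dx
  vel <- integral_velocity(trajectory$times, I)
  idx <- 2:(k - 1)
  ## drop snapshots whose front is near the right boundary
  guard <- max(1L, trajectory$grid$n - 10L)
  cmax <- trajectory$params$c_max
  ok <- trajectory$values[idx, guard, drop = TRUE] <= 0.5 * cmax
  v_ok <- vel[ok]
  if (length(v_ok) == 0L) v_ok <- vel
  tail_n <- max(1L, ceiling(length(v_ok) / 3))
  plateau <- mean(v_ok[(length(v_ok) - tail_n + 1L):length(v_ok)])
  out <- list(times = trajectory$times[idx], velocity = vel, plateau = plateau)
  class(out) <- "wave_velocity"
  out
}

#' Position of the concentration front
#'
#' Scans from the substrate (left) end and linearly interpolates the first
#' downcrossing of `level * c_max` between node positions
#' `x_i = (i - 1) dx`.
#'
#' @param field A [concentration_field_1d()].
#' @param level Crossing level as a fraction of `c_max` (default 0.5).
#' @param c_max Maximum concentration (default 1).
#' @return Front position, m.
#' @export
front_position <- function(field, level = 0.5, c_max = 1) {
  stopifnot(inherits(field, "conc_field_1d"))
  lev <- level * c_max
  v <- field$values
  if (all(v < lev)) stop("field entirely below level", call. = FALSE)
  if (all(v >= lev)) stop("field entirely above level", call. = FALSE)
  i <- which(v[-length(v)] >= lev & v[-1L] < lev)[1L]
  if (is.na(i)) stop("no downcrossing of level found", call. = FALSE)
  x <- grid_1d_positions(field$grid)
  frac <- (v[i] - lev) / (v[i] - v[i + 1L])
  x[i] + frac * field$grid$dx
}

#' Width and maximum slope of the concentration front
#'
#' Width is the distance between the interpolated 0.9 and 0.1 `c_max`
#' crossings; max slope is the largest backward-difference magnitude.
#' Steeper fronts (larger max slope, smaller width) arise for larger
#' particle size `lambda`.
#'
#' @inheritParams front_position
#' @return List with `width` (m) and `max_slope` (1/m).
#' @export
front_steepness <- function(field, c_max = 1) {
  stopifnot(inherits(field, "conc_field_1d"))
  x90 <- tryCatch(front_position(field, 0.9, c_max), error = function(e)
    stop("field does not cross 0.9 * c_max", call. = FALSE))
  x10 <- tryCatch(front_position(field, 0.1, c_max), error = function(e)
    stop("field does not cross 0.1 * c_max", call. = FALSE))
  slope <- max(abs(backward_diff_1d(field$values, field$grid$dx)))
  list(width = x10 - x90, max_slope = slope)
}

#' Extract one snapshot of a 1D trajectory as a field
#'
#' @param trajectory A `wave_1d` object.
#' @param i Snapshot index (1-based); negative counts from the end.
#' @return A [concentration_field_1d()].
#' @export
snapshot_1d <- function(trajectory, i = -1L) {
  stopifnot(inherits(trajectory, "wave_1d"))
  k <- length(trajectory$times)
  if (i < 0) i <- k + 1L + i
  if (i < 1L || i > k) stop("snapshot index out of range", call. = FALSE)
  concentration_field_1d(trajectory$grid, trajectory$values[i, ],
                         time = trajectory$times[i],
                         c_max = trajectory$params$c_max)
}
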