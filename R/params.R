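## Parameter and grid constructors. All quantities are SI unless noted;
## concentrations are dimensionless in [0, c_max].

stop_param <- function(key, msg) {
  stop(sprintf("invalid parameter '%s': %s", key, msg), call. = FALSE)
}

check_positive <- function(x, key, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 ||
      (finite && !is.finite(x)))
    stop_param(key, "must be a single positive number")
  as.numeric(x)
}

check_count <- function(x, key, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x))
    stop_param(key, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

#' Parameters of the 1D spatial adsorption equation
#'
#' The one-dimensional model describes irreversible attachment of platelets
#' to a substrate-seeded aggregate.  Its rate combines a volumetric
#' binding-site term `C / lambda` (cavity filling within the aggregate) and
#' a surface term `|dC/dx|` (free column ends that start new layers), both
#' damped by the saturation factor `(1 - C / c_max)`.
#'
#' Three variants are supported:
#' \describe{
#'   \item{`"full"`}{`dC/dt = k_eff (1 - C/c_max) (C/lambda + |dC/dx|)`,
#'     the two-binding-site multilayer model.}
#'   \item{`"bet"`}{`dC/dt = k_eff (1 - C/c_max) |dC/dx|`, the single-site
#'     (BET-like) reduction without the volumetric term.}
#'   \item{`"rosen"`}{`dC/dt = -k_eff dC/dx`, the non-saturating reduction,
#'     i.e. pure advection of the profile at speed `k_eff`.}
#' }
#'
#' @param lambda Characteristic particle (platelet) size, m.  Controls the
#'   weight of the volumetric term and thereby the front steepness.
#' @param k_eff Adhesion efficiency coefficient, m/s.  The free-platelet
#'   concentration of the suspension is absorbed into this constant.
#' @param c_max Maximum (packing) concentration, dimensionless; default 1.
#' @param variant One of `"full"`, `"bet"`, `"rosen"`.
#' @return An object of class `adsorption_params`.
#' @examples
#' adsorption_params(lambda = 1e-6, k_eff = 5e-7)
#' @export
adsorption_params <- function(lambda = 1e-6, k_eff = 5e-7, c_max = 1,
                              variant = c("full", "bet", "rosen")) {
  variant <- match.arg(variant)
  out <- list(
    lambda = check_positive(lambda, "lambda"),
    k_eff = check_positive(k_eff, "k_eff"),
    c_max = check_positive(c_max, "c_max"),
    variant = variant
  )
  class(out) <- "adsorption_params"
  out
}

#' Uniform 1D grid
#'
#' Concentration values are stored at nodes `x_i = (i - 1) dx`,
#' `i = 1..n_cells`, with `dx = length / n_cells`.
#'
#' @param length Domain length L, m.
#' @param n_cells Number of nodes.
#' @return An object of class `grid_1d` with fields `length`, `n`, `dx`.
#' @export
grid_1d <- function(length = 1e-4, n_cells = 100L) {
  out <- list(
    length = check_positive(length, "length"),
    n = check_count(n_cells, "n_cells", min = 3L)
  )
  out$dx <- out$length / out$n
  class(out) <- "grid_1d"
  out
}

#' Node positions of a 1D grid
#' @param grid A [grid_1d()] object.
#' @return Numeric vector of x positions, m.
#' @export
grid_1d_positions <- function(grid) {
  (seq_len(grid$n) - 1) * grid$dx
}

#' 1D concentration field
#'
#' @param grid A [grid_1d()] object.
#' @param values Concentration per node (dimensionless).  Defaults to the
#'   substrate seed: `c_max` at the first node, zero elsewhere.
#' @param time Current time, s.
#' @param c_max Upper bound used for the default seed and validation.
#' @return An object of class `conc_field_1d`.
#' @export
concentration_field_1d <- function(grid, values = NULL, time = 0, c_max = 1) {
  stopifnot(inherits(grid, "grid_1d"))
  if (is.null(values)) {
    values <- numeric(grid$n)
    values[1L] <- c_max
  }
  if (length(values) != grid$n)
    stop_param("values", sprintf("length %d does not match grid (%d nodes)",
                                 length(values), grid$n))
  if (any(!is.finite(values)))
    stop_param("values", "must be finite")
  if (any(values < 0) || any(values > c_max + 1e-12))
    stop_param("values", sprintf("must lie in [0, %g]", c_max))
  out <- list(grid = grid, values = as.numeric(values), time = as.numeric(time))
  class(out) <- "conc_field_1d"
  out
}

#' Explicit-Euler stability bound for the 1D model
#'
#' CFL-type bound `dt <= safety * dx / (k_eff * (1 + dx / lambda))` covering
#' the advective surface term and the volumetric growth term.
#'
#' @param params [adsorption_params()].
#' @param grid [grid_1d()].
#' @param safety Safety factor in (0, 1]; default 0.5.
#' @return Maximum stable time step, s.
#' @export
stable_dt_1d <- function(params, grid, safety = 0.5) {
  stopifnot(inherits(params, "adsorption_params"), inherits(grid, "grid_1d"))
  check_positive(safety, "safety")
  safety * grid$dx / (params$k_eff * (1 + grid$dx / params$lambda))
}

#' Fluid parameters of the channel flow
#'
#' Defaults correspond to blood plasma treated as a Newtonian incompressible
#' fluid.
#'
#' @param rho Density, kg/m^3 (default 1060).
#' @param nu Kinematic viscosity, m^2/s (default 5e-6).
#' @return An object of class `fluid_params`.
#' @export
fluid_params <- function(rho = 1060, nu = 5e-6) {
  out <- list(rho = check_positive(rho, "rho"), nu = check_positive(nu, "nu"))
  class(out) <- "fluid_params"
  out
}

#' Rectangular channel grid (2D, staggered layout)
#'
#' The channel occupies `[0, length] x [0, height]` with the inlet A at
#' x = 0, outlet B at x = length, top wall C at y = height and bottom wall D
#' (where the injury sits) at y = 0.  Pressure lives at cell centers
#' `((i - 0.5) dx, (j - 0.5) dy)`; u at vertical faces `x = i dx`; v at
#' horizontal faces `y = j dy`.
#'
#' @param length Channel length L, m (default 15e-5).
#' @param height Channel height M, m (default 5e-5).
#' @param nx,ny Cell counts along x and y (defaults 150 and 50, i.e.
#'   1 micron cells).
#' @return An object of class `channel_grid` with spacings `dx`, `dy`.
#' @export
channel_grid <- function(length = 15e-5, height = 5e-5, nx = 150L, ny = 50L) {
  out <- list(
    length = check_positive(length, "length"),
    height = check_positive(height, "height"),
    nx = check_count(nx, "nx", min = 3L),
    ny = check_count(ny, "ny", min = 3L)
  )
  out$dx <- out$length / out$nx
  out$dy <- out$height / out$ny
  class(out) <- "channel_grid"
  out
}

#' Cell-center coordinates of a channel grid
#' @param grid A [channel_grid()] object.
#' @return List with numeric vectors `x` (length nx) and `y` (length ny), m.
#' @export
cell_centers <- function(grid) {
  list(x = (seq_len(grid$nx) - 0.5) * grid$dx,
       y = (seq_len(grid$ny) - 0.5) * grid$dy)
}

#' Inlet/outlet boundary condition for the channel flow
#'
#' Two variants are available for the open sides A (inlet) and B (outlet):
#' \describe{
#'   \item{`"pressure_gradient"`}{Dirichlet pressures at A and B differing
#'     by `delta_p` (inlet high), with zero-gradient velocity at both open
#'     sides.}
#'   \item{`"velocity_profile"`}{A parabolic inlet profile
#'     `u(y) = wall_shear * y (M - y) / M`, whose wall slope is `wall_shear`
#'     and peak is `wall_shear * M / 4`, with a zero-gradient outflow at B.}
#' }
#' The defaults (30 Pa and 1000 1/s) produce approximately equivalent
#' unobstructed velocity fields in the default channel.
#'
#' @param variant `"pressure_gradient"` or `"velocity_profile"`.
#' @param delta_p Pressure drop over the channel, Pa (pressure variant).
#' @param wall_shear Inlet wall shear rate, 1/s (velocity variant).
#' @return An object of class `flow_bc`.
#' @export
flow_bc <- function(variant = c("pressure_gradient", "velocity_profile"),
                    delta_p = 30, wall_shear = 1000) {
  variant <- match.arg(variant)
  chk <- function(x, key) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
      stop_param(key, "must be a single non-negative number")
  }
  if (variant == "pressure_gradient") chk(delta_p, "delta_p")
  else chk(wall_shear, "wall_shear")
  out <- list(variant = variant, delta_p = as.numeric(delta_p),
              wall_shear = as.numeric(wall_shear))
  class(out) <- "flow_bc"
  out
}

#' Parameters of the 2D thrombus growth model
#'
#' In two dimensions the adhesion efficiency is shear-dependent:
#' `k_eff` is replaced by `k_adh * gamma`, where `gamma` is the local shear
#' rate of the fluid, and a convective redistribution term
#' `- k_rol div(v C)` models the movability of loosely bound platelets at
#' the thrombus boundary.  Cells whose concentration reaches `c_b` become
#' part of the rigid obstacle (no-slip for the flow).
#'
#' @param k_adh Adhesion coefficient, m (default 8e-11); the adhesion
#'   velocity scale is `k_adh * gamma`.
#' @param k_rol Platelet movability coefficient, dimensionless
#'   (default 7e-5).
#' @param lambda Characteristic platelet size, m (default 3e-6).
#' @param c_b Obstacle threshold concentration, dimensionless (default 0.9).
#' @param c_max Maximum concentration, dimensionless (default 1).
#' @return An object of class `thrombus_params`.
#' @export
thrombus_params <- function(k_adh = 8e-11, k_rol = 7e-5, lambda = 3e-6,
                            c_b = 0.9, c_max = 1) {
  if (!is.numeric(k_rol) || length(k_rol) != 1L || is.na(k_rol) || k_rol < 0)
    stop_param("k_rol", "must be a single non-negative number")
  out <- list(
    k_adh = check_positive(k_adh, "k_adh"),
    k_rol = as.numeric(k_rol),
    lambda = check_positive(lambda, "lambda"),
    c_b = check_positive(c_b, "c_b"),
    c_max = check_positive(c_max, "c_max")
  )
  if (out$c_b > out$c_max)
    stop_param("c_b", sprintf("must satisfy 0 < c_b <= c_max (= %g)", out$c_max))
  class(out) <- "thrombus_params"
  out
}

#' Injury patch on the bottom wall
#'
#' The injury is an initial condition: concentration 1 on the wall-adjacent
#' row of cells whose centers fall in the half-open segment
#' `[center - l0/2, center + l0/2)`.  The midpoint also defines the station
#' `l*` at which the cross-section wave velocity is measured.
#'
#' @param l0 Injury length, m (default 15e-6).
#' @param center Position of the injury midpoint along the bottom wall, m;
#'   default `NULL` places it at mid-channel.
#' @return An object of class `injury_spec`.
#' @export
injury_spec <- function(l0 = 15e-6, center = NULL) {
  out <- list(l0 = check_positive(l0, "l0"),
              center = if (is.null(center)) NULL else
                check_positive(center, "center"))
  class(out) <- "injury_spec"
  out
}

#' Resolve the injury midpoint against a grid
#'
#' Returns the station `l*` used by [cross_section_velocity()] and the
#' shape extents: the injury's `center` if given, else mid-wall.
#'
#' @param injury [injury_spec()].
#' @param grid [channel_grid()].
#' @return Position along wall D, m.
#' @export
injury_center <- function(injury, grid) {
  if (is.null(injury$center)) grid$length / 2 else injury$center
}
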