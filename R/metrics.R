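## Quantitative diagnostics: cross-section wave velocity, thrombus area and
## shape extents.

new_metrics_series <- function(times, values, metric, params = NULL) {
  stopifnot(length(times) == length(values))
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  out <- list(times = times, values = values, metric = metric, params = params)
  class(out) <- "metrics_series"
  out
}

#' Cross-section wave velocity of a coupled run
#'
#' The 2D analogue of the 1D front velocity: the time derivative of the
#' y-integral of the concentration along the vertical line `x = l*`,
#' `V = d/dt int_0^M C(l*, y) dy`, computed by central differences over the
#' recorded snapshots.  `l*` defaults to the injury midpoint fixed at
#' t = 0.
#'
#' @param sim A `thrombus_sim` object with at least 3 snapshots.
#' @param l_star Station along the channel, m; default the injury midpoint.
#' @return A `metrics_series` (m/s) at the interior snapshot times.
#' @export
cross_section_velocity <- function(sim, l_star = NULL) {
  stopifnot(inherits(sim, "thrombus_sim"))
  if (is.null(l_star)) l_star <- injury_center(sim$injury, sim$grid)
  if (l_star < 0 || l_star > sim$grid$length)
    stop("l_star outside the domain", call. = FALSE)
  k <- length(sim$times)
  if (k < 3L) stop("need at least 3 snapshots", call. = FALSE)
  i_star <- pmin(pmax(1L, as.integer(round(l_star / sim$grid$dx + 0.5))),
                 sim$grid$nx)
  I <- vapply(sim$conc, function(C) sum(C[i_star, ]) * sim$grid$dy, 0)
  vel <- integral_velocity(sim$times, I)
  new_metrics_series(sim$times[2:(k - 1L)], vel, "cross_section_velocity",
                     params = sim$params)
}

#' Thrombus area
#'
#' Area of the rigid thrombus: number of cells at or above the obstacle
#' threshold times the cell area.
#'
#' @param C Interior concentration matrix.
#' @param c_b Obstacle threshold.
#' @param grid [channel_grid()].
#' @return Area, m^2.
#' @export
thrombus_area <- function(C, c_b, grid) {
  C <- interior_conc(C)
  sum(C >= c_b) * grid$dx * grid$dy
}

#' Thrombus extents and height
#'
#' Shape descriptors of the thrombus (cells with `C >= c_b`): distances
#' from the injury midpoint to the farthest masked cell center against
#' (upstream) and with (downstream) the flow, and the height of the
#' farthest masked cell above wall D (top edge of that cell).  A
#' downstream extent exceeding the upstream extent is the torch-like
#' elongation with the flow.
#'
#' @param C Interior concentration matrix.
#' @param c_b Obstacle threshold.
#' @param injury_center Injury midpoint along the bottom wall, m.
#' @param grid [channel_grid()].
#' @return List with `upstream`, `downstream` and `height`, m.
#' @export
thrombus_extents <- function(C, c_b, injury_center, grid) {
  C <- interior_conc(C)
  idx <- which(C >= c_b, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty thrombus", call. = FALSE)
  xc <- (idx[, 1L] - 0.5) * grid$dx
  list(upstream = max(0, injury_center - min(xc)),
       downstream = max(0, max(xc) - injury_center),
       height = max(idx[, 2L]) * grid$dy)
}

#' Area time series of a coupled run
#'
#' @param sim A `thrombus_sim` object.
#' @return A `metrics_series` of thrombus area, m^2.
#' @export
thrombus_area_series <- function(sim) {
  stopifnot(inherits(sim, "thrombus_sim"))
  a <- vapply(sim$conc, thrombus_area, 0, c_b = sim$params$c_b, grid = sim$grid)
  new_metrics_series(sim$times, a, "thrombus_area", params = sim$params)
}

#' Convert a metrics series to a tidy data frame
#'
#' @param x A `metrics_series`.
#' @param run_id Identifier column value.
#' @param ... Unused.
#' @return data.frame with columns run_id, metric, time, value.
#' @export
as.data.frame.metrics_series <- function(x, run_id = "run", ...) {
  data.frame(run_id = run_id, metric = x$metric, time = x$times,
             value = x$values, stringsAsFactors = FALSE)
}
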