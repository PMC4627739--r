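## print / summary / plot methods for the simulation result classes.

#' @exportS3Method
print.adsorption_params <- function(x, ...) {
  cat(sprintf("1D adsorption parameters (variant '%s')\n", x$variant))
  cat(sprintf("  lambda = %g m, k_eff = %g m/s, c_max = %g\n",
              x$lambda, x$k_eff, x$c_max))
  invisible(x)
}

#' @exportS3Method
print.wave_1d <- function(x, ...) {
  cat(sprintf("1D adsorption trajectory ('%s'): %d snapshots to t = %g s on %d nodes (dx = %g m)\n",
              x$params$variant, length(x$times), max(x$times), x$grid$n,
              x$grid$dx))
  if (x$boundary_reached)
    cat("  note: front reached the right boundary; velocities there are unreliable\n")
  invisible(x)
}

#' @exportS3Method
summary.wave_1d <- function(object, ...) {
  v <- wave_velocity_1d(object)
  last <- snapshot_1d(object, -1L)
  st <- tryCatch(front_steepness(last, c_max = object$params$c_max),
                 error = function(e) list(width = NA_real_,
                                          max_slope = NA_real_))
  out <- list(plateau_velocity = v$plateau, n_snapshots = length(object$times),
              t_end = max(object$times), front_width = st$width,
              max_slope = st$max_slope,
              boundary_reached = object$boundary_reached)
  class(out) <- "summary.wave_1d"
  out
}

#' @exportS3Method
print.summary.wave_1d <- function(x, ...) {
  cat(sprintf("plateau velocity: %.4g m/s\n", x$plateau_velocity))
  cat(sprintf("front width (0.9-0.1): %.4g m, max slope: %.4g 1/m\n",
              x$front_width, x$max_slope))
  cat(sprintf("%d snapshots to t = %g s%s\n", x$n_snapshots, x$t_end,
              if (x$boundary_reached) " (front hit right boundary)" else ""))
  invisible(x)
}

#' Plot 1D concentration profiles over time
#' @param x A `wave_1d` object.
#' @param every Plot every k-th snapshot (default spreads ~8 profiles).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.wave_1d <- function(x, every = NULL, ...) {
  k <- length(x$times)
  if (is.null(every)) every <- max(1L, k %/% 8L)
  sel <- unique(c(seq(1L, k, by = every), k))
  graphics::matplot(grid_1d_positions(x$grid), t(x$values[sel, , drop = FALSE]),
                    type = "l", lty = 1, col = grDevices::hcl.colors(length(sel), "Blues3", rev = TRUE),
                    xlab = "x (m)", ylab = "concentration", ...)
  invisible(x)
}

#' @exportS3Method
print.wave_velocity <- function(x, ...) {
  cat(sprintf("front velocity series (%d points), plateau %.4g m/s\n",
              length(x$velocity), x$plateau))
  invisible(x)
}

#' @exportS3Method
print.flow_field <- function(x, ...) {
  g <- x$grid
  cat(sprintf("staggered flow field on %d x %d cells (%g x %g m)\n",
              g$nx, g$ny, g$length, g$height))
  cat(sprintf("  max |u| = %.4g m/s, max |v| = %.4g m/s, p range [%.4g, %.4g] Pa\n",
              max(abs(x$u)), max(abs(x$v)), min(x$p), max(x$p)))
  invisible(x)
}

#' Plot the speed magnitude of a flow field
#' @param x A `flow_field`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.flow_field <- function(x, ...) {
  g <- x$grid
  uc <- 0.5 * (x$u[1:g$nx, , drop = FALSE] + x$u[2:(g$nx + 1L), , drop = FALSE])
  vc <- 0.5 * (x$v[, 1:g$ny, drop = FALSE] + x$v[, 2:(g$ny + 1L), drop = FALSE])
  cc <- cell_centers(g)
  graphics::image(cc$x, cc$y, sqrt(uc^2 + vc^2), xlab = "x (m)",
                  ylab = "y (m)", main = "speed (m/s)", useRaster = TRUE, ...)
  invisible(x)
}

#' @exportS3Method
print.thrombus_sim <- function(x, ...) {
  cat(sprintf("coupled thrombus growth: %d snapshots to t = %g s on %d x %d cells\n",
              length(x$times), max(x$times), x$grid$nx, x$grid$ny))
  cat(sprintf("  %d steps, %d flow refreshes, %d masked cells (area %.3g m^2)\n",
              x$steps, x$refreshes, sum(x$mask),
              thrombus_area(x$conc[[length(x$conc)]], x$params$c_b, x$grid)))
  if (x$outlet_reached) cat("  note: thrombus reached the outlet column\n")
  invisible(x)
}

#' @exportS3Method
summary.thrombus_sim <- function(object, ...) {
  Cfin <- object$conc[[length(object$conc)]]
  ext <- tryCatch(thrombus_extents(Cfin, object$params$c_b,
                                   injury_center(object$injury, object$grid),
                                   object$grid),
                  error = function(e) list(upstream = NA_real_,
                                           downstream = NA_real_,
                                           height = NA_real_))
  out <- list(t_end = max(object$times),
              area = thrombus_area(Cfin, object$params$c_b, object$grid),
              upstream = ext$upstream, downstream = ext$downstream,
              height = ext$height, steps = object$steps,
              refreshes = object$refreshes,
              outlet_reached = object$outlet_reached)
  class(out) <- "summary.thrombus_sim"
  out
}

#' @exportS3Method
print.summary.thrombus_sim <- function(x, ...) {
  cat(sprintf("t = %g s: area %.4g m^2, extents %.4g m upstream / %.4g m downstream, height %.4g m\n",
              x$t_end, x$area, x$upstream, x$downstream, x$height))
  cat(sprintf("%d steps, %d flow refreshes%s\n", x$steps, x$refreshes,
              if (x$outlet_reached) ", outlet reached" else ""))
  invisible(x)
}

#' Plot the final concentration field of a coupled run
#' @param x A `thrombus_sim`.
#' @param snapshot Snapshot index (default last).
#' @param ... Passed to [graphics::image()].
#' @export
plot.thrombus_sim <- function(x, snapshot = NULL, ...) {
  if (is.null(snapshot)) snapshot <- length(x$conc)
  cc <- cell_centers(x$grid)
  C <- x$conc[[snapshot]]
  graphics::image(cc$x, cc$y, C, zlim = c(0, x$params$c_max),
                  col = grDevices::gray.colors(64, start = 1, end = 0),
                  xlab = "x (m)", ylab = "y (m)",
                  main = sprintf("concentration, t = %g s", x$times[snapshot]),
                  useRaster = TRUE, ...)
  graphics::contour(cc$x, cc$y, C, levels = x$params$c_b, add = TRUE,
                    col = "red", drawlabels = FALSE)
  invisible(x)
}

#' @exportS3Method
print.metrics_series <- function(x, ...) {
  cat(sprintf("metric '%s': %d points, t in [%g, %g] s, last value %.4g\n",
              x$metric, length(x$times), min(x$times), max(x$times),
              x$values[length(x$values)]))
  invisible(x)
}

#' Plot a metric series over time
#' @param x A `metrics_series`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.metrics_series <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "b", xlab = "time (s)",
                 ylab = x$metric, ...)
  invisible(x)
}
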