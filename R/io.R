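## Structured outputs: CSV field dumps (with self-describing headers), legacy
## ASCII VTK structured grids, tidy metric series, and JSON run manifests.
## All writers are deterministic: identical inputs give bit-identical files.

## shortest decimal representation that round-trips exactly
fmt_num <- function(x) {
  s <- trimws(formatC(x, format = "g", digits = 15))
  for (d in c(16L, 17L)) {
    bad <- suppressWarnings(as.numeric(s)) != x
    if (!any(bad)) break
    s[bad] <- trimws(formatC(x[bad], format = "g", digits = d))
  }
  s
}

#' Write a scalar field to disk
#'
#' CSV layout: comment header lines (axes, spacings in m, the cell-center
#' coordinate convention with origin at the inlet/bottom-wall corner),
#' then one line per y row (j = 1..ny) holding the nx values along x.
#' VTK layout: legacy ASCII STRUCTURED_POINTS with one named scalar array.
#'
#' @param field `nx x ny` matrix (x along rows).
#' @param path Output file path.
#' @param format `"csv"` or `"vtk"`.
#' @param name Field name recorded in the header.
#' @param grid [channel_grid()] supplying the spacings.
#' @param units Unit string recorded in the header.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path, format = c("csv", "vtk"), name = "field",
                        grid = NULL, units = "dimensionless") {
  format <- match.arg(format)
  stopifnot(is.matrix(field), !is.null(grid))
  con <- tryCatch(suppressWarnings(file(path, "wb")), error = function(e)
    stop(sprintf("cannot write to '%s'", path), call. = FALSE))
  on.exit(close(con))
  nx <- nrow(field); ny <- ncol(field)
  if (format == "csv") {
    hdr <- c(
      sprintf("# field: %s", name),
      sprintf("# units: %s", units),
      sprintf("# nx: %d  ny: %d", nx, ny),
      sprintf("# dx: %s m  dy: %s m", fmt_num(grid$dx), fmt_num(grid$dy)),
      "# layout: one line per y row (j = 1..ny), nx comma-separated values along x",
      "# coordinates: cell centers at ((i - 0.5) dx, (j - 0.5) dy), origin at the inlet / bottom-wall corner"
    )
    body <- vapply(seq_len(ny), function(j)
      paste(fmt_num(field[, j]), collapse = ","), "")
    writeLines(c(hdr, body), con)
  } else {
    writeLines(c(
      "# vtk DataFile Version 3.0",
      sprintf("thrombosim field %s (%s)", name, units),
      "ASCII",
      "DATASET STRUCTURED_POINTS",
      sprintf("DIMENSIONS %d %d 1", nx, ny),
      sprintf("ORIGIN %s %s 0", fmt_num(grid$dx / 2), fmt_num(grid$dy / 2)),
      sprintf("SPACING %s %s 1", fmt_num(grid$dx), fmt_num(grid$dy)),
      sprintf("POINT_DATA %d", nx * ny),
      sprintf("SCALARS %s double 1", name),
      "LOOKUP_TABLE default",
      vapply(seq_len(ny), function(j)
        paste(fmt_num(field[, j]), collapse = " "), "")
    ), con)
  }
  invisible(path)
}

#' Read back a CSV field written by [write_field()]
#'
#' @param path CSV file path.
#' @return `nx x ny` matrix.
#' @export
read_field_csv <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  rows <- lapply(strsplit(body, ","), as.numeric)
  matrix(unlist(rows), nrow = length(rows[[1L]]), ncol = length(rows))
}

#' Write a flow field (u, v, p, shear rate) as VTK
#'
#' Cell-centered interpolation of the staggered velocities, written as a
#' VECTORS array plus SCALARS arrays for u, v, p, gamma and divergence in
#' one legacy ASCII file.
#'
#' @param flow A `flow_field`.
#' @param path Output path.
#' @param grid [channel_grid()]; defaults to the field's grid.
#' @return `path`, invisibly.
#' @export
write_flow_vtk <- function(flow, path, grid = flow$grid) {
  nx <- grid$nx; ny <- grid$ny
  uc <- 0.5 * (flow$u[1:nx, , drop = FALSE] + flow$u[2:(nx + 1L), , drop = FALSE])
  vc <- 0.5 * (flow$v[, 1:ny, drop = FALSE] + flow$v[, 2:(ny + 1L), drop = FALSE])
  gam <- shear_rate_field(flow, grid)
  div <- divergence(flow, grid)
  con <- tryCatch(suppressWarnings(file(path, "wb")), error = function(e)
    stop(sprintf("cannot write to '%s'", path), call. = FALSE))
  on.exit(close(con))
  row_of <- function(m, j) paste(fmt_num(m[, j]), collapse = " ")
  scalar_block <- function(name, m)
    c(sprintf("SCALARS %s double 1", name), "LOOKUP_TABLE default",
      vapply(seq_len(ny), row_of, "", m = m))
  vec_rows <- vapply(seq_len(ny), function(j)
    paste(sprintf("%s %s 0", fmt_num(uc[, j]), fmt_num(vc[, j])),
          collapse = " "), "")
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "thrombosim flow field (u v in m/s, p in Pa, gamma in 1/s)",
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d 1", nx, ny),
    sprintf("ORIGIN %s %s 0", fmt_num(grid$dx / 2), fmt_num(grid$dy / 2)),
    sprintf("SPACING %s %s 1", fmt_num(grid$dx), fmt_num(grid$dy)),
    sprintf("POINT_DATA %d", nx * ny),
    "VECTORS velocity double",
    vec_rows,
    scalar_block("u", uc),
    scalar_block("v", vc),
    scalar_block("p", flow$p),
    scalar_block("gamma", gam),
    scalar_block("divergence", div)
  ), con)
  invisible(path)
}

#' Write a 1D trajectory as CSV
#'
#' Columns: time (s), then one column per node (`x_<position>` in m).
#'
#' @param trajectory A `wave_1d` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "wave_1d"))
  x <- grid_1d_positions(trajectory$grid)
  df <- data.frame(time = trajectory$times, trajectory$values)
  names(df) <- c("time", sprintf("x_%s", fmt_num(x)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write metric series as tidy CSV
#'
#' @param series A `metrics_series` or list of them.
#' @param path Output path.
#' @param run_id Run identifier recorded per row.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(series, path, run_id = "run") {
  if (inherits(series, "metrics_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, as.data.frame, run_id = run_id))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## FNV-1a hash of a string, as hex; used for config fingerprints.  Arithmetic
## split into 16-bit halves so every intermediate stays exactly representable.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b))
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (h0 * p + (h1 * p %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a JSON run manifest
#'
#' Records the full configuration, a fingerprint of it, package version,
#' and any run statistics passed in `info` (step counts, flow refreshes,
#' timings).
#'
#' @param path Output path.
#' @param cfg Configuration list.
#' @param info Named list of run statistics.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, cfg, info = list()) {
  manifest <- list(
    package = "thrombosim",
    version = as.character(utils::packageVersion("thrombosim")),
    config_hash = fnv1a(yaml::as.yaml(cfg)),
    config = cfg,
    run = info
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
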