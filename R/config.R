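## YAML configuration layer.  One human-readable file, SI units throughout;
## every default equals the reference parameter set (the standard 2D growth
## setup and the standard 1D run).

#' Default simulation configuration
#'
#' The defaults describe the reference 2D growth setup: a 150 x 50 micron
#' channel at 1 micron resolution, blood-like fluid (rho = 1060 kg/m^3,
#' nu = 5e-6 m^2/s), pressure-gradient boundary conditions with
#' delta_p = 30 Pa (equivalently a wall shear rate near 1000 1/s),
#' a 15 micron mid-wall injury, and thrombus parameters k_adh = 8e-11 m,
#' k_rol = 7e-5, lambda = 3e-6 m, C_B = 0.9.  The `one_d` section holds the
#' standard 1D run (lambda = 1e-6 m, k_eff = 5e-7 m/s).
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    model = "2d",
    t_end = 100,
    one_d = list(lambda = 1e-6, k_eff = 5e-7, c_max = 1, variant = "full",
                 length = 1e-4, n_cells = 100L, t_end = 60),
    thrombus = list(k_adh = 8e-11, k_rol = 7e-5, lambda = 3e-6,
                    c_b = 0.9, c_max = 1),
    fluid = list(rho = 1060, nu = 5e-6),
    flow_bc = list(variant = "pressure_gradient", delta_p = 30,
                   wall_shear = 1000),
    injury = list(l0 = 15e-6, center = NULL),
    grid = list(length = 15e-5, height = 5e-5, nx = 150L, ny = 50L),
    numerics = list(safety = 0.5, flow_mode = "stokes", refresh_every = 100L,
                    shear_mode = "strain", tol = 1e-5),
    output = list(dir = "thrombosim-out", format = "csv", record_every = NULL)
  )
}

## Recursive merge of a user config over the defaults, erroring on keys the
## defaults do not know, reported with their dot path.
merge_config <- function(defaults, user, path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(user))
    stop(sprintf("config section '%s' must be a mapping",
                 paste(path, collapse = ".")), call. = FALSE)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L)
    stop(sprintf("unknown config key '%s'",
                 paste(c(path, unknown[1L]), collapse = ".")), call. = FALSE)
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.null(defaults[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      c(path, key))
    } else {
      defaults[key] <- user[key]      # [<- keeps explicit NULLs
    }
  }
  defaults
}

require_key <- function(ok, key, msg) {
  if (!ok) stop(sprintf("invalid config value at '%s': %s", key, msg),
                call. = FALSE)
}

pos_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0

#' Validate a configuration
#'
#' Checks positivity, threshold and geometry invariants, naming the
#' offending dot-separated key on failure.
#'
#' @param cfg Configuration list.
#' @return The validated configuration, invisibly.
#' @export
validate_config <- function(cfg) {
  require_key(cfg$model %in% c("1d", "2d"), "model", "must be '1d' or '2d'")
  for (k in c("lambda", "k_eff", "c_max", "length"))
    require_key(pos_num(cfg$one_d[[k]]), paste0("one_d.", k),
                "must be a positive number")
  require_key(cfg$one_d$variant %in% c("full", "bet", "rosen"),
              "one_d.variant", "must be one of full, bet, rosen")
  for (k in c("k_adh", "lambda", "c_b", "c_max"))
    require_key(pos_num(cfg$thrombus[[k]]), paste0("thrombus.", k),
                "must be a positive number")
  require_key(is.numeric(cfg$thrombus$k_rol) && cfg$thrombus$k_rol >= 0,
              "thrombus.k_rol", "must be non-negative")
  require_key(cfg$thrombus$c_b <= cfg$thrombus$c_max, "thrombus.c_b",
              sprintf("must not exceed c_max = %g", cfg$thrombus$c_max))
  for (k in c("rho", "nu"))
    require_key(pos_num(cfg$fluid[[k]]), paste0("fluid.", k),
                "must be a positive number")
  require_key(cfg$flow_bc$variant %in% c("pressure_gradient",
                                         "velocity_profile"),
              "flow_bc.variant",
              "must be 'pressure_gradient' or 'velocity_profile'")
  require_key(pos_num(cfg$flow_bc$delta_p), "flow_bc.delta_p",
              "must be a positive number")
  require_key(pos_num(cfg$flow_bc$wall_shear), "flow_bc.wall_shear",
              "must be a positive number")
  for (k in c("length", "height"))
    require_key(pos_num(cfg$grid[[k]]), paste0("grid.", k),
                "must be a positive number")
  for (k in c("nx", "ny"))
    require_key(pos_num(cfg$grid[[k]]) && cfg$grid[[k]] == round(cfg$grid[[k]]),
                paste0("grid.", k), "must be a positive integer")
  require_key(pos_num(cfg$injury$l0), "injury.l0", "must be a positive number")
  require_key(cfg$injury$l0 <= cfg$grid$length, "injury.l0",
              "must not exceed the channel length")
  if (!is.null(cfg$injury$center)) {
    ctr <- cfg$injury$center
    require_key(pos_num(ctr) &&
                  ctr - cfg$injury$l0 / 2 >= -1e-12 &&
                  ctr + cfg$injury$l0 / 2 <= cfg$grid$length + 1e-12,
                "injury.center", "injury must lie within the bottom wall")
  }
  require_key(pos_num(cfg$t_end), "t_end", "must be a positive number")
  require_key(pos_num(cfg$numerics$safety) && cfg$numerics$safety <= 1,
              "numerics.safety", "must lie in (0, 1]")
  require_key(cfg$numerics$flow_mode %in% c("stokes", "march"),
              "numerics.flow_mode", "must be 'stokes' or 'march'")
  require_key(cfg$numerics$shear_mode %in% c("strain", "dudy"),
              "numerics.shear_mode", "must be 'strain' or 'dudy'")
  invisible(cfg)
}

#' Load a configuration file
#'
#' Reads a YAML file, fills omitted fields with the reference defaults
#' ([default_config()]), rejects unknown keys and validates invariants.
#' An empty file yields exactly the default configuration.
#'
#' @param path Path to a YAML file.
#' @return Validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_config(), user)
  validate_config(cfg)
  cfg
}

#' Write a configuration file
#'
#' @param cfg Configuration list.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Apply dot-path overrides to a configuration
#'
#' @param cfg Configuration list.
#' @param sets Character vector of `key.path=value` strings (values parsed
#'   as YAML, so numbers and booleans work).
#' @return The updated, validated configuration.
#' @export
config_set <- function(cfg, sets) {
  for (s in sets) {
    eq <- regexpr("=", s, fixed = TRUE)
    if (eq < 0) stop(sprintf("override '%s' is not key=value", s),
                     call. = FALSE)
    key <- substr(s, 1L, eq - 1L)
    val <- yaml::yaml.load(substr(s, eq + 1L, nchar(s)))
    if (is.character(val)) {       # YAML 1.1 misses floats like 4e-5
      num <- suppressWarnings(as.numeric(val))
      if (!is.na(num)) val <- num
    }
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    node <- list(); tip <- val
    for (p in rev(parts)) { node <- list(); node[[p]] <- tip; tip <- node }
    cfg <- merge_config(cfg, tip)
  }
  validate_config(cfg)
  cfg
}

## Construct the typed parameter objects a 2D run needs from a config.
config_objects_2d <- function(cfg) {
  list(
    grid = channel_grid(cfg$grid$length, cfg$grid$height,
                        cfg$grid$nx, cfg$grid$ny),
    fluid = fluid_params(cfg$fluid$rho, cfg$fluid$nu),
    bc = flow_bc(cfg$flow_bc$variant, cfg$flow_bc$delta_p,
                 cfg$flow_bc$wall_shear),
    params = thrombus_params(cfg$thrombus$k_adh, cfg$thrombus$k_rol,
                             cfg$thrombus$lambda, cfg$thrombus$c_b,
                             cfg$thrombus$c_max),
    injury = injury_spec(cfg$injury$l0, cfg$injury$center)
  )
}

config_objects_1d <- function(cfg) {
  list(
    params = adsorption_params(cfg$one_d$lambda, cfg$one_d$k_eff,
                               cfg$one_d$c_max, cfg$one_d$variant),
    grid = grid_1d(cfg$one_d$length, cfg$one_d$n_cells)
  )
}
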