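## Shared fixtures, built in code.

## small channel used by the cheaper 2D tests
small_grid <- function(nx = 30L, ny = 10L)
  channel_grid(length = nx * 1e-6, height = ny * 1e-6, nx = nx, ny = ny)

## monotone decreasing profile in [0, 1] with a fixed seed
random_front_profile <- function(n, seed) {
  set.seed(seed)
  sort(runif(n), decreasing = TRUE)
}

## a minimal thrombus_sim-like object for metric tests
fake_sim <- function(times, conc, grid, injury = injury_spec(),
                     params = thrombus_params()) {
  out <- list(times = times, conc = conc, grid = grid, injury = injury,
              params = params)
  class(out) <- "thrombus_sim"
  out
}

## memoized store for expensive acceptance runs shared between tests
acceptance_env <- new.env(parent = emptyenv())

acceptance_run <- function(name, build) {
  if (is.null(acceptance_env[[name]])) acceptance_env[[name]] <- build()
  acceptance_env[[name]]
}
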