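# Analytic path fixtures and a per-run cache of steady-cycle simulations.

# closed circle sampled uniformly in angle; `dup` repeats the first sample
# at the end (as simulated cycles are stored)
make_circle <- function(r = 0.1, n = 1000, center = c(0, 0), period = 2 * pi,
                        dup = FALSE) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  if (!dup) th <- th[-(n + 1)]
  tibble::tibble(
    t = th / (2 * pi) * period,
    q1 = th, q2 = rep(pi / 4, length(th)),
    x = center[1] + r * cos(th),
    y = center[2] + r * sin(th)
  )
}

make_ellipse <- function(a = 0.2, b = 0.1, n = 1000, dup = FALSE) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  if (!dup) th <- th[-(n + 1)]
  tibble::tibble(
    t = th,
    q1 = th, q2 = rep(pi / 4, length(th)),
    x = a * cos(th), y = b * sin(th)
  )
}

# memoized steady-cycle simulations shared across test files
.sim_cache <- new.env(parent = emptyenv())
get_sim <- function(E, gravity = TRUE) {
  key <- paste0("E", E, if (!gravity) "_g0")
  if (is.null(.sim_cache[[key]])) {
    params <- if (gravity) arm_params() else arm_params(g_mag = 0)
    .sim_cache[[key]] <-
      simulate_steady_cycle(params, controller_params(E = E))
  }
  .sim_cache[[key]]
}

E_GRID <- c(0, 10, 20, 30, 40, 50)

get_sims_list <- function() {
  sims <- lapply(E_GRID, get_sim)
  names(sims) <- as.character(E_GRID)
  sims
}
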