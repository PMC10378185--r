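#' Growth-law parameters
#'
#' Bundles the parameters of a single population's growth law: the maximum
#' per-capita growth rate `r` (1/day), the carrying capacity `K`, the
#' loss-of-contact-inhibition exponent `v` (Richards shape; `v = 1` gives the
#' Verhulst/logistic model), and the initial population size `N0`. `K` and
#' `N0` share units — absolute cell counts internally; use
#' [density_to_count()] to convert surface densities at the boundary.
#'
#' @param r maximum per-capita growth rate (1/day), `>= 0`.
#' @param K carrying capacity, `> 0`.
#' @param N0 initial population size, `> 0`.
#' @param v loss-of-contact-inhibition exponent, `> 0` (default 1).
#' @return an object of class `growth_params`.
#' @examples
#' growth_params(r = 0.8, K = 1e6, N0 = 1e4)
#' @export
growth_params <- function(r, K, N0, v = 1) {
  vals <- c(r = r, K = K, v = v, N0 = N0)
  if (!all(is.finite(vals))) stop("growth parameters must be finite")
  if (r < 0) stop("`r` must be non-negative")
  if (K <= 0) stop("`K` must be positive")
  if (v <= 0) stop("`v` must be positive")
  if (N0 <= 0) stop("`N0` must be positive")
  structure(list(r = r, K = K, v = v, N0 = N0), class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("Growth parameters: r = %.4g /day, K = %.4g, v = %.4g, N0 = %.4g\n",
              x$r, x$K, x$v, x$N0))
  invisible(x)
}

#' Convert between surface density and absolute count
#'
#' Experimental seeding densities and capacities are reported per cm^2; the
#' simulation state is an absolute cell count. The default surface is a T25
#' flask (25 cm^2).
#'
#' @param density cells per cm^2.
#' @param count absolute cell count.
#' @param area culture surface in cm^2 (default 25, a T25 flask).
#' @return the converted quantity.
#' @export
density_to_count <- function(density, area = 25) density * area

#' @rdname density_to_count
#' @export
count_to_density <- function(count, area = 25) count / area

model_names <- c("verhulst", "richards", "gompertz")

match_model <- function(model) match.arg(model, model_names)

#' Closed-form Verhulst (logistic) trajectory
#'
#' Exact solution of the logistic equation
#' `dN/dt = r N (1 - N/K)`: `N(t) = K / (1 + ((K - N0)/N0) exp(-r t))`.
#'
#' @param params a [growth_params()] object (with `v = 1`).
#' @param t time(s) in days, `>= 0`.
#' @return population size(s) at `t`.
#' @examples
#' p <- growth_params(r = 1, K = 100, N0 = 1)
#' verhulst_solution(p, log(99))  # midpoint K/2 = 50
#' @export
verhulst_solution <- function(params, t) {
  stopifnot(inherits(params, "growth_params"))
  if (any(t < 0)) stop("`t` must be non-negative")
  with(params, K / (1 + ((K - N0) / N0) * exp(-r * t)))
}

#' Closed-form growth trajectories
#'
#' Exact solutions for the three growth laws:
#' Verhulst `N = K/(1 + ((K-N0)/N0) e^{-rt})`; Richards (generalized
#' logistic) `N = K (1 + Q e^{-r v t})^{-1/v}` with `Q = (K/N0)^v - 1`;
#' Gompertz `N = K (N0/K)^{exp(-r t)}`.
#'
#' @inheritParams verhulst_solution
#' @param model one of `"verhulst"`, `"richards"`, `"gompertz"`.
#' @return population size(s) at `t`.
#' @export
growth_solution <- function(model, params, t) {
  model <- match_model(model)
  stopifnot(inherits(params, "growth_params"))
  if (any(t < 0)) stop("`t` must be non-negative")
  with(params, switch(model,
    verhulst = K / (1 + ((K - N0) / N0) * exp(-r * t)),
    richards = {
      Q <- expm1(v * (log(K) - log(N0)))  # (K/N0)^v - 1, stable for small v
      K * (1 + Q * exp(-r * v * t))^(-1 / v)
    },
    gompertz = K * exp(log(N0 / K) * exp(-r * t))
  ))
}

#' Growth-law right-hand sides
#'
#' `dN/dt` for the three growth laws: Richards
#' `N r (1 - (N/K)^v)`, Verhulst the same with `v = 1`, and Gompertz
#' `N r ln(K/N)` (defined as 0 at `N = 0`, its limit).
#'
#' @inheritParams growth_solution
#' @param N population size, `>= 0`.
#' @return the instantaneous growth rate `dN/dt`.
#' @export
growth_rhs <- function(model, params, N) {
  model <- match_model(model)
  stopifnot(inherits(params, "growth_params"))
  if (any(N < 0)) stop("`N` must be non-negative")
  with(params, switch(model,
    verhulst = N * r * (1 - N / K),
    richards = N * r * (1 - (N / K)^v),
    gompertz = ifelse(N == 0, 0, N * r * log(K / N))
  ))
}

#' Simulate a single-population growth trajectory
#'
#' Numerically integrates the chosen growth law from `N0` over `t_grid` with
#' the adaptive Dormand-Prince solver (`rtol = 1e-8`, `atol = 1e-6`). For the
#' Verhulst model the result matches [verhulst_solution()] to better than
#' 1e-6 relative error.
#'
#' @inheritParams growth_solution
#' @param t_grid strictly increasing times (days) starting at 0.
#' @param population_id label for the resulting curve.
#' @return a `growth_curve` data frame with columns `time_days`, `count`,
#'   `population_id`.
#' @export
simulate_growth <- function(model, params, t_grid,
                            population_id = "simulated") {
  model <- match_model(model)
  stopifnot(inherits(params, "growth_params"))
  if (t_grid[1] != 0) stop("`t_grid` must start at 0")
  if (any(diff(t_grid) <= 0)) stop("`t_grid` must be strictly increasing")
  sol <- ode_rk45(function(t, y) growth_rhs(model, params, y),
                  y0 = params$N0, times = t_grid)
  growth_curve(t_grid, as.numeric(sol[, 1]), population_id)
}

#' Cell-count time series container
#'
#' @param times days since seeding, non-negative and strictly increasing.
#' @param counts observed (or simulated) cell counts, positive.
#' @param population_id label of the cell line or simulation.
#' @return a data frame of class `growth_curve` with columns `time_days`,
#'   `count`, `population_id`.
#' @export
growth_curve <- function(times, counts, population_id = "population") {
  if (length(times) != length(counts)) stop("times/counts length mismatch")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (any(times < 0)) stop("`times` must be non-negative")
  if (any(counts <= 0)) stop("`counts` must be positive")
  structure(data.frame(time_days = as.numeric(times),
                       count = as.numeric(counts),
                       population_id = as.character(population_id),
                       stringsAsFactors = FALSE),
            class = c("growth_curve", "data.frame"))
}

#' Multi-clone shared-capacity competition system
#'
#' A set of clones coupled through one spatial resource: each clone `i` grows
#' as `dN_i/dt = N_i r_i (1 - (sum_j N_j/K_j)^v)`, so every clone's growth
#' slows by the same occupancy term `sum_j N_j/K_j`. The contact-inhibition
#' exponent `v` is shared by all clones of a cell line (default 1, the
#' logistic case used for clone simulations).
#'
#' @param clone_ids unique clone labels.
#' @param r per-clone maximum growth rates (1/day), `>= 0`.
#' @param K per-clone carrying capacities, `> 0`.
#' @param v shared loss-of-contact-inhibition exponent, `> 0`.
#' @param state optional initial clone sizes (`>= 0`); may be set later.
#' @return an object of class `clone_system`.
#' @examples
#' clone_system(c("A", "B"), r = c(1, 0.6), K = c(1e6, 3e6),
#'              state = c(1e4, 1e4))
#' @export
clone_system <- function(clone_ids, r, K, v = 1, state = NULL) {
  n <- length(clone_ids)
  if (anyDuplicated(clone_ids)) stop("clone IDs must be unique")
  if (length(r) != n || length(K) != n) stop("r/K must match clone_ids length")
  if (any(!is.finite(r)) || any(r < 0)) stop("`r` must be finite and >= 0")
  if (any(!is.finite(K)) || any(K <= 0)) stop("`K` must be finite and > 0")
  if (!is.finite(v) || v <= 0) stop("`v` must be finite and > 0")
  if (!is.null(state)) {
    if (length(state) != n) stop("`state` must match the number of clones")
    if (any(state < 0)) stop("clone sizes must be non-negative")
  }
  structure(list(clone_ids = as.character(clone_ids),
                 r = as.numeric(r), K = as.numeric(K), v = v,
                 state = if (is.null(state)) NULL else as.numeric(state)),
            class = "clone_system")
}

#' @export
print.clone_system <- function(x, ...) {
  cat(sprintf("Clone system: %d clones, shared v = %.3g\n",
              length(x$clone_ids), x$v))
  df <- data.frame(clone = x$clone_ids, r = x$r, K = x$K)
  if (!is.null(x$state)) df$N0 <- x$state
  print(df, row.names = FALSE)
  invisible(x)
}

clone_rhs <- function(system, N) {
  occ <- sum(N / system$K)
  N * system$r * (1 - occ^system$v)
}

#' Simulate clonal competition under a shared carrying capacity
#'
#' Integrates the coupled clone system (see [clone_system()]) over `t_grid`.
#' When the seeded occupancy `sum_i N_i(0)/K_i` is below 1, every clone's
#' trajectory is non-decreasing — growth of the population can never be
#' negative — so harvesting can only be delayed, never missed.
#'
#' @param system a [clone_system()] with `state` set (or supply `state`).
#' @param t_grid strictly increasing times (days) starting at 0.
#' @param state optional initial sizes overriding `system$state`.
#' @return matrix of clone sizes, `length(t_grid)` rows by one column per
#'   clone, with `t_grid` as the `time` attribute.
#' @export
simulate_clones <- function(system, t_grid, state = NULL) {
  stopifnot(inherits(system, "clone_system"))
  state <- if (is.null(state)) system$state else as.numeric(state)
  if (is.null(state)) stop("initial clone sizes required")
  if (length(state) != length(system$clone_ids)) {
    stop("state length does not match number of clones")
  }
  if (any(state < 0)) stop("clone sizes must be non-negative")
  if (t_grid[1] != 0) stop("`t_grid` must start at 0")
  sol <- ode_rk45(function(t, y) clone_rhs(system, y),
                  y0 = state, times = t_grid)
  colnames(sol) <- system$clone_ids
  attr(sol, "time") <- t_grid
  sol
}
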