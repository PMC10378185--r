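#' Serial-passage schedule
#'
#' A culture schedule: cells are seeded at `density` cells/cm^2 on a surface
#' of `area` cm^2 (default a T25 flask), grown for `interval` days, harvested,
#' and re-seeded at the same total density with the harvest's clone
#' frequencies; repeated for `n_passages` passages.
#'
#' @param density seeding density in cells/cm^2.
#' @param interval splitting interval in days.
#' @param n_passages number of passages to simulate.
#' @param area culture surface in cm^2 (default 25).
#' @return an object of class `passage_schedule`.
#' @export
passage_schedule <- function(density, interval, n_passages = 30, area = 25) {
  if (density <= 0 || interval <= 0 || area <= 0) {
    stop("density, interval and area must be positive")
  }
  if (n_passages < 0) stop("`n_passages` must be non-negative")
  structure(list(density = density, interval = interval,
                 n_passages = as.integer(n_passages), area = area),
            class = "passage_schedule")
}

#' Simulate clonal competition across serial passages
#'
#' Each passage seeds `density * area` total cells split among the clones at
#' the current frequencies, integrates the shared-capacity competition ODE
#' ([simulate_clones()]) for `interval` days, and records the harvest sizes
#' and frequencies; the harvest frequencies become the seeding frequencies
#' of the next passage (deterministic dilution, no bottleneck sampling).
#' Seeding must stay below the capacity surface (`sum_i N_i(0)/K_i < 1`),
#' the precondition under which population growth is provably non-negative.
#'
#' @param system a [clone_system()]; `K` in absolute cell counts.
#' @param schedule a [passage_schedule()].
#' @param initial_frequencies clone frequencies at the first seeding
#'   (summing to 1).
#' @return an object of class `passage_series`: matrices `sizes` and
#'   `frequencies` (`n_passages` rows = harvests, one column per clone),
#'   plus the seeded state and the schedule. With `n_passages = 0` the
#'   outcome is the seeded state itself.
#' @examples
#' sys <- clone_system(c("fast", "dense"), r = c(1, 0.6), K = c(1e6, 3e6))
#' run_passage_series(sys, passage_schedule(1e4, 7, 10), c(0.5, 0.5))
#' @export
run_passage_series <- function(system, schedule, initial_frequencies) {
  stopifnot(inherits(system, "clone_system"),
            inherits(schedule, "passage_schedule"))
  n <- length(system$clone_ids)
  if (length(initial_frequencies) != n) {
    stop("`initial_frequencies` must have one entry per clone")
  }
  if (any(initial_frequencies < 0) ||
      abs(sum(initial_frequencies) - 1) > 1e-8) {
    stop("initial frequencies must be non-negative and sum to 1")
  }
  seed_total <- schedule$density * schedule$area
  freqs <- initial_frequencies / sum(initial_frequencies)
  seeded <- seed_total * freqs
  if (sum(seeded / system$K) >= 1) {
    stop("seeding occupancy sum(N_i/K_i) must be < 1: nonnegative growth ",
         "is only guaranteed below the capacity surface")
  }

  np <- schedule$n_passages
  sizes <- matrix(NA_real_, nrow = np, ncol = n,
                  dimnames = list(NULL, system$clone_ids))
  fmat <- sizes
  state <- seeded
  for (p in seq_len(np)) {
    traj <- simulate_clones(system, c(0, schedule$interval), state = state)
    harvest <- traj[2L, ]
    sizes[p, ] <- harvest
    fr <- harvest / sum(harvest)
    fmat[p, ] <- fr
    state <- seed_total * fr
  }
  structure(list(clone_ids = system$clone_ids, seeded = seeded,
                 initial_frequencies = freqs, sizes = sizes,
                 frequencies = fmat, schedule = schedule, system = system),
            class = "passage_series")
}

#' @export
print.passage_series <- function(x, ...) {
  s <- x$schedule
  cat(sprintf(
    "Passage series: %d clones, %d passage(s), %.4g cells/cm^2 every %.3g d\n",
    length(x$clone_ids), s$n_passages, s$density, s$interval))
  if (s$n_passages > 0) {
    last <- x$frequencies[s$n_passages, ]
    cat("  final harvest frequencies:\n")
    print(round(last, 6))
  }
  invisible(x)
}

#' @export
plot.passage_series <- function(x, ..., log_freq = FALSE) {
  np <- x$schedule$n_passages
  if (np == 0) stop("nothing to plot: 0 passages")
  f <- x$frequencies
  graphics::matplot(seq_len(np), f, type = "b", pch = 19, lty = 1,
                    log = if (log_freq) "y" else "",
                    xlab = "passage", ylab = "clone frequency at harvest", ...)
  graphics::legend("topleft", legend = x$clone_ids, col = seq_len(ncol(f)),
                   lty = 1, pch = 19, bty = "n")
  invisible(x)
}

#' Signed-magnitude outcome of a two-clone competition
#'
#' `sgn(CloneK - Cloner) * log10(max(Cloner, CloneK))`: positive values mean
#' the K-selected clone wins (K selection), negative values the r-selected
#' clone (r selection); the magnitude is the size (log10 cells) of the
#' winning clone.
#'
#' @param clone_r_size final size of the r-selected clone (`>= 0`).
#' @param clone_k_size final size of the K-selected clone (`>= 0`).
#' @return the signed magnitude; 0 (with a warning) when both sizes are 0.
#' @examples
#' outcome_metric(1e3, 1e6)  #  +6: K clone wins at 10^6 cells
#' outcome_metric(1e6, 1e3)  #  -6: r clone wins
#' @export
outcome_metric <- function(clone_r_size, clone_k_size) {
  if (clone_r_size < 0 || clone_k_size < 0) stop("sizes must be non-negative")
  if (clone_r_size == 0 && clone_k_size == 0) {
    warning("both clone sizes are 0; outcome metric undefined, returning 0")
    return(0)
  }
  sign(clone_k_size - clone_r_size) * log10(max(clone_r_size, clone_k_size))
}

#' Evolutionary-steering heatmap over culture schedules
#'
#' Runs [run_passage_series()] for every (seeding density, splitting
#' interval) combination and evaluates [outcome_metric()] on the designated
#' r-selected and K-selected clones at the final harvest. Low densities and
#' long intervals leave room for exponential expansion and favor the
#' r-clone; high densities and short splits keep the culture near
#' confluence and favor the K-clone. Other clones in the system compete in
#' the simulation but do not enter the metric. Schedule cells whose seeding
#' exceeds the capacity surface are returned as `NA`.
#'
#' @param system a [clone_system()].
#' @param r_clone,k_clone clone IDs of the designated r- and K-selected
#'   clones.
#' @param densities seeding densities (cells/cm^2) — heatmap columns.
#' @param intervals splitting intervals (days) — heatmap rows.
#' @param n_passages passages per schedule (default 30).
#' @param initial_frequencies seeding frequencies (default uniform).
#' @param area culture surface (cm^2).
#' @return a `steering_heatmap` object: the metric matrix (`intervals` by
#'   `densities`) plus the grids.
#' @export
steering_heatmap <- function(system, r_clone, k_clone, densities, intervals,
                             n_passages = 30, initial_frequencies = NULL,
                             area = 25) {
  stopifnot(inherits(system, "clone_system"))
  if (length(densities) == 0 || length(intervals) == 0) {
    stop("density and interval grids must be non-empty")
  }
  ids <- system$clone_ids
  if (!(r_clone %in% ids) || !(k_clone %in% ids)) {
    stop("r_clone and k_clone must be clones of the system")
  }
  if (is.null(initial_frequencies)) {
    initial_frequencies <- rep(1 / length(ids), length(ids))
  }
  m <- matrix(NA_real_, nrow = length(intervals), ncol = length(densities),
              dimnames = list(interval = signif(intervals, 6),
                              density = signif(densities, 6)))
  for (i in seq_along(intervals)) {
    for (j in seq_along(densities)) {
      res <- tryCatch(
        run_passage_series(system,
                           passage_schedule(densities[j], intervals[i],
                                            n_passages, area),
                           initial_frequencies),
        error = function(e) NULL
      )
      if (is.null(res) || n_passages == 0) next
      final <- res$sizes[n_passages, ]
      m[i, j] <- outcome_metric(final[[r_clone]], final[[k_clone]])
    }
  }
  structure(list(metric = m, densities = densities, intervals = intervals,
                 r_clone = r_clone, k_clone = k_clone,
                 n_passages = n_passages),
            class = "steering_heatmap")
}

#' @export
print.steering_heatmap <- function(x, ...) {
  cat(sprintf(
    "Steering heatmap: %d interval(s) x %d densit(ies), %d passages\n",
    length(x$intervals), length(x$densities), x$n_passages))
  cat(sprintf("  metric range: [%.3g, %.3g] (+: %s wins, -: %s wins)\n",
              min(x$metric, na.rm = TRUE), max(x$metric, na.rm = TRUE),
              x$k_clone, x$r_clone))
  invisible(x)
}

#' @export
plot.steering_heatmap <- function(x, ...) {
  z <- t(x$metric)  # image(): x = densities, y = intervals
  zlim <- max(abs(z), na.rm = TRUE) * c(-1, 1)
  pal <- grDevices::colorRampPalette(c("firebrick", "white", "navy"))(101)
  graphics::image(log10(x$densities), x$intervals, z, zlim = zlim, col = pal,
                  xlab = "log10 seeding density (cells/cm^2)",
                  ylab = "splitting interval (days)",
                  main = sprintf("Competition outcome (+%s / -%s)",
                                 x$k_clone, x$r_clone), ...)
  invisible(x)
}

#' First passage at which one clone overtakes another
#'
#' @param outcome a [run_passage_series()] result.
#' @param clone_a,clone_b clone IDs.
#' @return the smallest passage index at which the harvest frequency of
#'   `clone_a` strictly exceeds that of `clone_b`, or `NA_integer_` if it
#'   never does.
#' @export
crossing_passage <- function(outcome, clone_a, clone_b) {
  stopifnot(inherits(outcome, "passage_series"))
  if (!(clone_a %in% outcome$clone_ids) || !(clone_b %in% outcome$clone_ids)) {
    stop("both clones must be present in the passage series")
  }
  above <- outcome$frequencies[, clone_a] > outcome$frequencies[, clone_b]
  if (!any(above)) return(NA_integer_)
  which(above)[1L]
}
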