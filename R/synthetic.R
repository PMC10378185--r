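#' Noisy observed growth curve from a known growth law
#'
#' Emulates daily cell counting: the exact model trajectory at the sampled
#' days, perturbed by multiplicative log-normal noise with coefficient of
#' variation `noise_cv` (mean-one multiplier, so counts are unbiased).
#' Deterministic for a fixed seed.
#'
#' @param params true [growth_params()].
#' @param schedule sampling times in days (default daily for 21 days).
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (default 0.05, i.e. 5% counting error).
#' @param model generating growth law.
#' @param seed RNG seed (optional).
#' @param population_id curve label.
#' @return a [growth_curve()].
#' @export
generate_growth_curve <- function(params, schedule = 0:21, noise_cv = 0.05,
                                  model = "verhulst", seed = NULL,
                                  population_id = "synthetic") {
  if (noise_cv < 0) stop("`noise_cv` must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  mu <- growth_solution(model, params, schedule)
  mult <- if (noise_cv == 0) rep(1, length(mu)) else {
    sdlog <- sqrt(log1p(noise_cv^2))
    exp(stats::rnorm(length(mu), -sdlog^2 / 2, sdlog))
  }
  growth_curve(schedule, mu * mult, population_id)
}

# clamp a clone parameter onto [0, 1] for the expression-signal link
param_to_signal <- function(value, range) {
  pmin(1, pmax(0, (value - range[1]) / (range[2] - range[1])))
}

#' Define a synthetic multi-line, multi-clone scenario
#'
#' Describes a panel of cell lines with known growth parameters and a clone
#' structure, from which growth curves ([generate_scenario_curves()]) and a
#' clone-structured expression matrix ([generate_population()]) can be
#' generated. The scenario itself is deterministic — changing the seed of
#' the generators changes noise realizations, never the structure.
#'
#' Line-level parameters span the experimentally observed ranges: seeding
#' densities 4.98-38.64e3 cells/cm^2 and carrying capacities 1.92-15.32e5
#' cells/cm^2 on a T25 flask (25 cm^2), growth rates 0.35-1.0 /day.
#' Carrying capacities are assigned in a fixed permutation so that `r` and
#' `K` are uncorrelated across lines. Each line carries two clones. In
#' `tradeoff_lines` the clones oppose: one gains 25% growth rate and loses
#' 25% capacity relative to the line, the other the reverse — a planted r/K
#' trade-off. In all other lines the two clones differ by +/-15% in *both*
#' parameters in the same direction: significantly different, but no
#' trade-off.
#'
#' Expression is negative-binomial (dispersion `nb_size`): most genes sit at
#' `base_mu`, while the genes of the r-driver (K-driver) set are scaled by
#' `1 + driver_amp * z`, `z` the clone's growth rate (capacity) normalized
#' to [0, 1] — so the driver sets' rank-AUC activity increases close to
#' linearly with the clone's parameter, and decoy sets carry no signal.
#'
#' @param n_lines number of cell lines (default 8; first `n_train` are the
#'   training set).
#' @param n_train training cell lines (default 5).
#' @param tradeoff_lines indices of lines given an opposing clone pair
#'   (default 1).
#' @param cells_per_clone cells sequenced per clone (default 40).
#' @param genes genes in the expression matrix (default 1000).
#' @param n_sets total gene sets, drivers included (default 25).
#' @param set_size genes per set (default 20, disjoint sets).
#' @param base_mu baseline negative-binomial mean per gene (default 2).
#' @param nb_size negative-binomial size (inverse dispersion, default 2).
#' @param driver_amp maximal fold boost of driver genes (default 4).
#' @param noise_cv counting noise for growth curves (default 0.05).
#' @param phase_probs cell-cycle phase proportions for G0G1, S, G2M
#'   (default 0.6, 0.2, 0.2).
#' @param area culture surface, cm^2.
#' @return an object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_lines = 8, n_train = 5, tradeoff_lines = 1,
                               cells_per_clone = 40, genes = 1000,
                               n_sets = 25, set_size = 20, base_mu = 2,
                               nb_size = 2, driver_amp = 4, noise_cv = 0.05,
                               phase_probs = c(0.6, 0.2, 0.2), area = 25) {
  if (n_sets * set_size > genes) stop("gene sets do not fit into the matrix")
  if (n_train >= n_lines) stop("need at least one validation line")
  if (abs(sum(phase_probs) - 1) > 1e-8) stop("phase_probs must sum to 1")

  line_ids <- sprintf("line%02d", seq_len(n_lines))
  r_line <- seq(0.35, 1.0, length.out = n_lines)
  # fixed permutation decorrelating K from r across the panel
  perm <- ((seq_len(n_lines) * 3L) %% n_lines) + 1L
  K_density <- seq(1.92e5, 15.32e5, length.out = n_lines)[perm]
  N0_density <- seq(4.98e3, 38.64e3, length.out = n_lines)
  K_count <- K_density * area
  N0_count <- N0_density * area
  # sample until just past the plateau, capped at the observed 6-21 d window
  duration <- pmin(21, pmax(6, ceiling(log(pmax((K_count - N0_count) /
                                                  N0_count, 2)) / r_line +
                                         4 / r_line)))
  lines <- data.frame(line = line_ids, r = r_line, K_density = K_density,
                      N0_density = N0_density, K = K_count, N0 = N0_count,
                      duration_days = duration, stringsAsFactors = FALSE)

  clones <- do.call(rbind, lapply(seq_len(n_lines), function(i) {
    if (i %in% tradeoff_lines) {
      mult_r <- c(1.25, 0.75); mult_K <- c(0.75, 1.25)
    } else {
      mult_r <- c(1.15, 0.85); mult_K <- c(1.15, 0.85)
    }
    data.frame(line = line_ids[i],
               clone_id = paste0(line_ids[i], c("_A", "_B")),
               r = r_line[i] * mult_r, K_density = K_density[i] * mult_K,
               K = K_count[i] * mult_K,
               tradeoff = i %in% tradeoff_lines, stringsAsFactors = FALSE)
  }))

  sets <- split(sprintf("g%04d", seq_len(n_sets * set_size)),
                rep(seq_len(n_sets), each = set_size))
  names(sets) <- c("driver_r", "driver_K",
                   sprintf("decoy_%02d", seq_len(n_sets - 2)))

  structure(list(lines = lines, clones = clones, gene_sets = sets,
                 train_lines = line_ids[seq_len(n_train)],
                 validation_lines = line_ids[(n_train + 1):n_lines],
                 cells_per_clone = cells_per_clone, genes = genes,
                 base_mu = base_mu, nb_size = nb_size,
                 driver_amp = driver_amp, noise_cv = noise_cv,
                 phase_probs = phase_probs, area = area,
                 r_signal_range = c(0.2, 1.3),
                 K_signal_range = c(1e5, 2.1e6) * area),
            class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(
    "Synthetic scenario: %d cell lines (%d train), %d clones, %d genes\n",
    nrow(x$lines), length(x$train_lines), nrow(x$clones), x$genes))
  cat(sprintf("  planted r/K trade-off in: %s\n",
              paste(unique(x$clones$line[x$clones$tradeoff]), collapse = ", ")))
  invisible(x)
}

#' Generate noisy growth curves for every line of a scenario
#'
#' @param scenario a [synthetic_scenario()].
#' @param seed RNG seed.
#' @return named list of [growth_curve()] objects, one per cell line, each
#'   sampled daily over the line's duration.
#' @export
generate_scenario_curves <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(seed)
  out <- list()
  for (i in seq_len(nrow(scenario$lines))) {
    li <- scenario$lines[i, ]
    p <- growth_params(r = li$r, K = li$K, N0 = li$N0)
    out[[li$line]] <- generate_growth_curve(
      p, schedule = 0:li$duration_days, noise_cv = scenario$noise_cv,
      population_id = li$line)
  }
  out
}

#' Generate a clone-structured single-cell expression matrix
#'
#' Draws negative-binomial counts for every cell of every clone of the
#' scenario, with the driver gene sets scaled by the clone's growth rate and
#' carrying capacity (see [synthetic_scenario()]), plus cell annotations and
#' the ground-truth parameter table for recovery tests.
#'
#' @param scenario a [synthetic_scenario()].
#' @param seed RNG seed (noise only; structure is fixed by the scenario).
#' @return list with `expression` (genes-by-cells integer matrix),
#'   `annotations` (cell_id, cell_line, clone_id, phase), `gene_sets`, and
#'   `truth` (the scenario's line and clone parameter tables).
#' @export
generate_population <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  sets <- scenario$gene_sets
  if (length(intersect(sets$driver_r, sets$driver_K))) {
    stop("driver gene sets overlap: confounded design")
  }
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(scenario$genes))
  idx_r <- match(sets$driver_r, genes)
  idx_K <- match(sets$driver_K, genes)

  n_cells <- nrow(scenario$clones) * scenario$cells_per_clone
  expr <- matrix(0L, nrow = scenario$genes, ncol = n_cells)
  ann <- vector("list", nrow(scenario$clones))
  cell <- 0L
  cell_ids <- character(n_cells)
  for (ci in seq_len(nrow(scenario$clones))) {
    cl <- scenario$clones[ci, ]
    z_r <- param_to_signal(cl$r, scenario$r_signal_range)
    z_K <- param_to_signal(cl$K, scenario$K_signal_range)
    mu <- rep(scenario$base_mu, scenario$genes)
    mu[idx_r] <- scenario$base_mu * (1 + scenario$driver_amp * z_r)
    mu[idx_K] <- scenario$base_mu * (1 + scenario$driver_amp * z_K)
    phases <- sample(c("G0G1", "S", "G2M"), scenario$cells_per_clone,
                     replace = TRUE, prob = scenario$phase_probs)
    for (j in seq_len(scenario$cells_per_clone)) {
      cell <- cell + 1L
      expr[, cell] <- stats::rnbinom(scenario$genes, mu = mu,
                                     size = scenario$nb_size)
      cell_ids[cell] <- sprintf("cell_%05d", cell)
    }
    ann[[ci]] <- data.frame(
      cell_id = cell_ids[(cell - scenario$cells_per_clone + 1L):cell],
      cell_line = cl$line, clone_id = cl$clone_id, phase = phases,
      stringsAsFactors = FALSE)
  }
  dimnames(expr) <- list(genes, cell_ids)
  list(expression = expr, annotations = do.call(rbind, ann),
       gene_sets = sets,
       truth = list(lines = scenario$lines, clones = scenario$clones,
                    driver_r = "driver_r", driver_K = "driver_K"))
}
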