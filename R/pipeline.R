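#' Pipeline configuration
#'
#' Collects every input path and tunable threshold of the end-to-end
#' analysis. All thresholds default to the values used throughout the
#' workflow — top 5% active genes, clone-pair alpha 0.1, FDR 0.05,
#' 200-feature cell filter — and are echoed into the run summary for
#' provenance. A config can also be read from YAML with
#' [read_pipeline_config()].
#'
#' @param counts path to the cell-count CSV (`time_days`, `count`,
#'   `population_id` = cell line).
#' @param expression path to the expression matrix (MTX or dense CSV).
#' @param annotations path to the cell annotation TSV.
#' @param gene_sets path to the gene-set GMT.
#' @param out_dir output directory (created if missing).
#' @param model growth law fitted to the count curves.
#' @param train_lines cell lines used to train biomarker models; the
#'   remaining lines are the validation set.
#' @param top_fraction,alpha,fdr_level,min_features,top_n thresholds (see
#'   details).
#' @param seed tie-breaking / reproducibility seed.
#' @param densities,intervals,n_passages,area steering-heatmap grids for
#'   cell lines with a flagged trade-off (defaults: 20 log-spaced densities
#'   over the observed seeding range 4.98e3-38.64e3 cells/cm^2, intervals
#'   1-10 days, 30 passages).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(counts, expression, annotations, gene_sets,
                            out_dir, model = "verhulst", train_lines,
                            top_fraction = 0.05, alpha = 0.1,
                            fdr_level = 0.05, min_features = 200, top_n = 5,
                            seed = 42,
                            densities = exp(seq(log(4.98e3), log(38.64e3),
                                                length.out = 20)),
                            intervals = 1:10, n_passages = 30, area = 25) {
  structure(list(counts = counts, expression = expression,
                 annotations = annotations, gene_sets = gene_sets,
                 out_dir = out_dir, model = model, train_lines = train_lines,
                 top_fraction = top_fraction, alpha = alpha,
                 fdr_level = fdr_level, min_features = min_features,
                 top_n = top_n, seed = seed, densities = densities,
                 intervals = intervals, n_passages = n_passages,
                 area = area),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with the fields of [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full density-dependent-selection analysis
#'
#' Executes the whole workflow: fit growth curves per cell line; score
#' per-cell gene-set activity; summarize medians per cell line and
#' cell-cycle grouping; train linear biomarker models of `r` and `K` on the
#' training lines and rank the top pathways; validate them on the full
#' panel with FDR control; predict per-cell growth parameters from the best
#' confirmed biomarkers; scan every cell line for r/K trade-offs between
#' its clones; and compute steering heatmaps for lines with a flagged
#' trade-off. Per-stage artifacts (CSV/JSON) are written under
#' `config$out_dir`; reruns with the same config and seed are
#' byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) the summary list, also written as `summary.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  curves <- read_growth_curves(config$counts)
  expr <- read_expression(config$expression)
  ann <- read_annotations(config$annotations)
  sets <- read_gmt(config$gene_sets)
  if (!any(ann$cell_id %in% colnames(expr))) {
    stop("annotations '", config$annotations,
         "' share no cell IDs with the expression matrix")
  }

  # -- stage 1: growth fitting per cell line ------------------------------
  fits <- lapply(curves, fit_growth, model = config$model)
  ok <- vapply(fits, function(f) f$converged && !f$degenerate, TRUE)
  if (!all(ok)) {
    stop("growth fitting failed for: ", paste(names(fits)[!ok], collapse = ", "))
  }
  targets <- list(
    r = vapply(fits, function(f) f$params$r, 0),
    K = vapply(fits, function(f) f$params$K, 0)
  )
  fit_table <- data.frame(
    cell_line = names(fits),
    r = targets$r, K = targets$K,
    N0 = vapply(fits, function(f) f$params$N0, 0),
    adj_r2 = vapply(fits, function(f) f$adj_r2, 0),
    aic = vapply(fits, function(f) f$aic, 0), stringsAsFactors = FALSE)
  utils::write.csv(fit_table, file.path(config$out_dir, "growth_fits.csv"),
                   row.names = FALSE)

  # -- stage 2: per-cell activity scores ----------------------------------
  expr <- filter_cells(expr, config$min_features)
  activity <- aucell_scores(expr, sets, top_fraction = config$top_fraction,
                            seed = config$seed)
  groupings <- c("all", "G0G1", "S", "G2M")
  medians <- lapply(stats::setNames(groupings, groupings), function(g) {
    suppressWarnings(median_activity_by_group(activity, ann, g))
  })

  # -- stage 3: biomarker training and validation -------------------------
  train <- intersect(config$train_lines, names(fits))
  if (length(train) < 3L) stop("fewer than 3 training cell lines available")
  models <- list(r = list(), K = list())
  for (tg in c("r", "K")) {
    for (g in groupings) {
      med <- medians[[g]]
      lines <- intersect(rownames(med), train)
      for (pw in colnames(med)) {
        models[[tg]][[paste(pw, g)]] <- fit_biomarker(
          stats::setNames(med[lines, pw], lines), targets[[tg]][lines],
          pathway = pw, target = tg, grouping = g)
      }
    }
  }
  top <- lapply(models, rank_pathways, top_n = config$top_n)
  validation <- validate_biomarkers(c(top$r, top$K), medians, targets,
                                    fdr_level = config$fdr_level)
  utils::write.csv(biomarker_table(validation$models),
                   file.path(config$out_dir, "biomarkers.csv"),
                   row.names = FALSE)

  pick_model <- function(tg) {
    cand <- Filter(function(m) m$target == tg, validation$confirmed)
    fallback <- FALSE
    if (length(cand) == 0L) {
      cand <- Filter(function(m) m$target == tg, validation$models)
      fallback <- TRUE
    }
    if (length(cand) == 0L) return(NULL)
    best <- cand[[order(-vapply(cand, function(m) m$adj_r2, 0))[1]]]
    best$fallback <- fallback
    best
  }
  r_model <- pick_model("r")
  K_model <- pick_model("K")
  if (is.null(r_model) || is.null(K_model)) {
    stop("biomarker stage produced no usable model for r and/or K")
  }

  # -- stage 4: clone predictions and trade-off scan ----------------------
  scans <- list()
  clone_means <- list()
  for (cl in sort(unique(ann$cell_line))) {
    preds <- suppressWarnings(
      clone_predictions(activity, ann, r_model, K_model, cell_line = cl))
    if (length(preds) < 2L) next
    sc <- scan_cell_line(preds, alpha = config$alpha)
    sc$cell_line <- cl
    scans[[cl]] <- sc
    clone_means[[cl]] <- data.frame(
      clone_id = vapply(preds, function(p) p$clone_id, ""),
      r_bar = vapply(preds, function(p) p$r_bar, 0),
      K_bar = vapply(preds, function(p) p$K_bar, 0),
      stringsAsFactors = FALSE)
  }
  if (length(scans) == 0L) {
    scan_table <- data.frame(clone_x = character(), clone_y = character(),
                             p_r = numeric(), p_K = numeric(),
                             tau_r = numeric(), tau_K = numeric(),
                             tradeoff = logical(), cell_line = character())
  } else {
    scan_table <- do.call(rbind, c(lapply(scans, as.data.frame),
                                   list(make.row.names = FALSE)))
  }
  utils::write.csv(scan_table, file.path(config$out_dir, "tradeoffs.csv"),
                   row.names = FALSE)

  # -- stage 5: steering heatmaps for trade-off lines ---------------------
  heatmaps <- list()
  hits <- scan_table[scan_table$tradeoff, , drop = FALSE]
  for (i in seq_len(nrow(hits))) {
    cl <- hits$cell_line[i]
    cm <- clone_means[[cl]]
    # r-selected clone of the pair = higher predicted growth rate
    pair <- c(hits$clone_x[i], hits$clone_y[i])
    pr <- cm$r_bar[match(pair, cm$clone_id)]
    r_clone <- pair[which.max(pr)]
    k_clone <- pair[which.min(pr)]
    sys <- clone_system(cm$clone_id, r = pmax(cm$r_bar, 0),
                        K = pmax(cm$K_bar, 1), v = 1)
    hm <- steering_heatmap(sys, r_clone, k_clone, config$densities,
                           config$intervals, config$n_passages,
                           area = config$area)
    utils::write.csv(hm$metric,
                     file.path(config$out_dir,
                               sprintf("steering_%s.csv", cl)))
    heatmaps[[cl]] <- hm
  }

  summary <- list(
    thresholds = config[c("model", "top_fraction", "alpha", "fdr_level",
                          "min_features", "top_n", "seed")],
    train_lines = train,
    validation_lines = setdiff(names(fits), train),
    growth_fits = fit_table,
    selected_biomarkers = list(
      r = list(pathway = r_model$pathway, grouping = r_model$grouping,
               adj_r2 = r_model$adj_r2, fdr = r_model$fdr,
               confirmed = !isTRUE(r_model$fallback)),
      K = list(pathway = K_model$pathway, grouping = K_model$grouping,
               adj_r2 = K_model$adj_r2, fdr = K_model$fdr,
               confirmed = !isTRUE(K_model$fallback))),
    confirmed_biomarkers = lapply(validation$confirmed, function(m) {
      list(pathway = m$pathway, grouping = m$grouping, target = m$target,
           adj_r2 = m$adj_r2, fdr = m$fdr)
    }),
    tradeoff_pairs = if (nrow(hits)) {
      hits[, c("cell_line", "clone_x", "clone_y", "p_r", "p_K",
               "tau_r", "tau_K")]
    } else NULL,
    steering_lines = names(heatmaps)
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(summary)
}

#' Run the analysis end-to-end on a synthetic scenario (in memory)
#'
#' Convenience wrapper chaining the pipeline stages on generated data
#' without file I/O: generates the scenario's growth curves and expression
#' population at `seed`, fits per-line growth parameters, scores activity,
#' trains/validates biomarker models, and scans every cell line for r/K
#' trade-offs. Used for recovery studies where the ground truth is known.
#'
#' @param scenario a [synthetic_scenario()].
#' @param seed RNG seed for the generated noise.
#' @param model growth law for curve fitting.
#' @param top_n,fdr_level,alpha,top_fraction,min_features thresholds as in
#'   [pipeline_config()].
#' @return list with `fits`, `targets`, `top` (per-target training ranking),
#'   `validation`, `selected` (r/K models used for prediction), `scans`
#'   (per cell line) and `flagged` (all flagged trade-off rows).
#' @export
run_synthetic_pipeline <- function(scenario, seed = 1, model = "verhulst",
                                   top_n = 5, fdr_level = 0.05, alpha = 0.1,
                                   top_fraction = 0.05, min_features = 200) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  curves <- generate_scenario_curves(scenario, seed = seed)
  pop <- generate_population(scenario, seed = seed + 1L)

  fits <- lapply(curves, fit_growth, model = model)
  targets <- list(r = vapply(fits, function(f) f$params$r, 0),
                  K = vapply(fits, function(f) f$params$K, 0))

  expr <- filter_cells(pop$expression, min_features)
  activity <- aucell_scores(expr, pop$gene_sets, top_fraction = top_fraction)
  groupings <- c("all", "G0G1", "S", "G2M")
  medians <- lapply(stats::setNames(groupings, groupings), function(g) {
    suppressWarnings(median_activity_by_group(activity, pop$annotations, g))
  })

  train <- scenario$train_lines
  models <- list(r = list(), K = list())
  for (tg in c("r", "K")) {
    for (g in groupings) {
      med <- medians[[g]]
      lines <- intersect(rownames(med), train)
      for (pw in colnames(med)) {
        models[[tg]][[paste(pw, g)]] <- fit_biomarker(
          stats::setNames(med[lines, pw], lines), targets[[tg]][lines],
          pathway = pw, target = tg, grouping = g)
      }
    }
  }
  top <- lapply(models, rank_pathways, top_n = top_n)
  validation <- validate_biomarkers(c(top$r, top$K), medians, targets,
                                    fdr_level = fdr_level)
  pick <- function(tg) {
    cand <- Filter(function(m) m$target == tg, validation$confirmed)
    if (length(cand) == 0L) {
      cand <- Filter(function(m) m$target == tg, validation$models)
    }
    if (length(cand) == 0L) return(NULL)
    cand[[order(-vapply(cand, function(m) m$adj_r2, 0))[1]]]
  }
  selected <- list(r = pick("r"), K = pick("K"))
  scans <- list()
  if (!is.null(selected$r) && !is.null(selected$K)) {
    for (cl in sort(unique(pop$annotations$cell_line))) {
      preds <- suppressWarnings(
        clone_predictions(activity, pop$annotations, selected$r, selected$K,
                          cell_line = cl))
      if (length(preds) < 2L) next
      sc <- scan_cell_line(preds, alpha = alpha)
      sc$cell_line <- cl
      scans[[cl]] <- sc
    }
  }
  flagged <- do.call(rbind, lapply(scans, function(s) {
    as.data.frame(s)[s$tradeoff, , drop = FALSE]
  }))
  list(fits = fits, targets = targets, top = top, validation = validation,
       selected = selected, scans = scans, flagged = flagged,
       truth = pop$truth)
}
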