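#' Per-clone growth-parameter predictions
#'
#' Applies confirmed biomarker models to per-cell activity scores and groups
#' the predicted growth rate and carrying capacity by clone. Only cells of
#' the phase grouping each biomarker was fitted on are used (e.g. G2M cells
#' for a "during G2M" growth-rate model); clones with fewer than `min_cells`
#' usable cells for either parameter are dropped with a warning, mirroring
#' the exclusion of clones with insufficient phase representation.
#'
#' @param activity cells-by-gene-sets score matrix ([aucell_scores()]).
#' @param annotations cell annotation data frame (see
#'   [median_activity_by_group()]); only cells of one cell line should be
#'   supplied (or filter by `cell_line`).
#' @param r_model,K_model non-degenerate [fit_biomarker()] models for the
#'   growth rate and the carrying capacity.
#' @param cell_line optional cell line to restrict to.
#' @param min_cells minimum usable cells per clone (default 2, required by
#'   the t-test).
#' @return list of `clone_prediction` objects, one per retained clone, each
#'   with `clone_id`, per-cell `r` and `K` predictions, their means `r_bar`,
#'   `K_bar`, and cell counts.
#' @export
clone_predictions <- function(activity, annotations, r_model, K_model,
                              cell_line = NULL, min_cells = 2L) {
  check_annotations(annotations)
  ann <- annotations
  if (!is.null(cell_line)) ann <- ann[ann$cell_line == cell_line, , drop = FALSE]
  ann <- ann[ann$cell_id %in% rownames(activity), , drop = FALSE]

  cells_for <- function(model, clone) {
    sub <- ann[ann$clone_id == clone, , drop = FALSE]
    if (model$grouping != "all") sub <- sub[sub$phase == model$grouping, , drop = FALSE]
    sub$cell_id
  }

  preds <- list()
  for (clone in sort(unique(ann$clone_id))) {
    r_cells <- cells_for(r_model, clone)
    K_cells <- cells_for(K_model, clone)
    if (length(r_cells) < min_cells || length(K_cells) < min_cells) {
      warning("clone ", clone, " has < ", min_cells,
              " cells in the required phase grouping; excluded")
      next
    }
    r_pred <- predict(r_model, activity[r_cells, r_model$pathway])
    K_pred <- predict(K_model, activity[K_cells, K_model$pathway])
    preds[[clone]] <- structure(
      list(clone_id = clone, r = as.numeric(r_pred), K = as.numeric(K_pred),
           r_bar = mean(r_pred), K_bar = mean(K_pred),
           n_r = length(r_pred), n_K = length(K_pred)),
      class = "clone_prediction")
  }
  preds
}

#' @export
print.clone_prediction <- function(x, ...) {
  cat(sprintf("Clone %s: r_bar = %.4g (n = %d), K_bar = %.4g (n = %d)\n",
              x$clone_id, x$r_bar, x$n_r, x$K_bar, x$n_K))
  invisible(x)
}

#' Test one clone pair for an r/K trade-off
#'
#' Compares two clones' per-cell predicted growth rates and carrying
#' capacities with two-sided equal-variance (classic Student) two-sample
#' t-tests, and computes the ratios `tau_r = r_bar_x / r_bar_y` and
#' `tau_K = K_bar_x / K_bar_y`. A trade-off is flagged when both p-values
#' are at or below `alpha` (default 0.1) *and* the ratios point in opposite
#' directions — one clone grows faster while the other packs denser:
#' `(tau_r < 1 & tau_K > 1) | (tau_r > 1 & tau_K < 1)`.
#'
#' @param pred_x,pred_y `clone_prediction` objects ([clone_predictions()]),
#'   each with at least 2 cells per parameter.
#' @param alpha significance threshold applied to both tests.
#' @param var_equal use the pooled-variance Student test (default `TRUE`);
#'   `FALSE` gives Welch.
#' @return a one-row data frame: `clone_x`, `clone_y`, `p_r`, `p_K`,
#'   `tau_r`, `tau_K`, `tradeoff`.
#' @export
tradeoff_test <- function(pred_x, pred_y, alpha = 0.1, var_equal = TRUE) {
  stopifnot(inherits(pred_x, "clone_prediction"),
            inherits(pred_y, "clone_prediction"))
  if (min(pred_x$n_r, pred_x$n_K, pred_y$n_r, pred_y$n_K) < 2L) {
    stop("each clone needs >= 2 cells per parameter for the t-test")
  }
  p_r <- safe_t_pvalue(pred_x$r, pred_y$r, var_equal)
  p_K <- safe_t_pvalue(pred_x$K, pred_y$K, var_equal)
  tau_r <- pred_x$r_bar / pred_y$r_bar
  tau_K <- pred_x$K_bar / pred_y$K_bar
  opposing <- (tau_r < 1 && tau_K > 1) || (tau_r > 1 && tau_K < 1)
  data.frame(clone_x = pred_x$clone_id, clone_y = pred_y$clone_id,
             p_r = p_r, p_K = p_K, tau_r = tau_r, tau_K = tau_K,
             tradeoff = is.finite(p_r) && is.finite(p_K) &&
               p_r <= alpha && p_K <= alpha && opposing,
             stringsAsFactors = FALSE)
}

safe_t_pvalue <- function(x, y, var_equal) {
  # identical constant samples have no variance to test against
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  stats::t.test(x, y, var.equal = var_equal)$p.value
}

#' Scan a cell line for r/K trade-offs between its clones
#'
#' Runs [tradeoff_test()] on every unordered clone pair of a cell line
#' (`n(n-1)/2` tests for `n` clones). No cross-pair multiplicity correction
#' is applied at this step.
#'
#' @param predictions list of `clone_prediction` objects for one cell line
#'   (>= 2 clones).
#' @param alpha,var_equal passed to [tradeoff_test()].
#' @return a `tradeoff_scan` data frame, one row per pair, with columns
#'   `clone_x`, `clone_y`, `p_r`, `p_K`, `tau_r`, `tau_K`, `tradeoff`.
#' @export
scan_cell_line <- function(predictions, alpha = 0.1, var_equal = TRUE) {
  if (length(predictions) < 2L) stop("need >= 2 clones to scan for trade-offs")
  n <- length(predictions)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      rows[[length(rows) + 1L]] <-
        tradeoff_test(predictions[[i]], predictions[[j]], alpha, var_equal)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("tradeoff_scan", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' @export
print.tradeoff_scan <- function(x, ...) {
  cat(sprintf("r/K trade-off scan: %d clone pair(s), alpha = %.2g\n",
              nrow(x), attr(x, "alpha")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  n_hit <- sum(x$tradeoff)
  cat(if (n_hit == 0) "No r/K trade-off detected.\n"
      else sprintf("%d potential r/K trade-off(s) flagged.\n", n_hit))
  invisible(x)
}
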