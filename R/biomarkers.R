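#' Fit a linear biomarker model for a growth parameter
#'
#' Ordinary least squares of a growth parameter on pathway activity,
#' `delta = a * p + c`, where `delta` is the per-cell-line fitted growth rate
#' `r` or carrying capacity `K` and `p` is the cell line's median pathway
#' activity (one observation per cell line). Reports the slope `a`,
#' intercept `c`, Pearson correlation, adjusted R-squared (one predictor)
#' and the two-sided p-value of the slope.
#'
#' @param activity named numeric vector of median pathway activity, one
#'   value per cell line.
#' @param targets named numeric vector of the fitted parameter (`r` or `K`)
#'   for the same cell lines.
#' @param pathway gene-set name (metadata).
#' @param target which parameter is modeled, `"r"` or `"K"`.
#' @param grouping cell-cycle grouping the activities came from (metadata).
#' @return an object of class `biomarker_fit` with `slope`, `intercept`,
#'   `pearson`, `r2`, `adj_r2`, `p_value`, `n`, and a `degenerate` flag set
#'   when the activity has zero variance (such models are excluded from
#'   ranking). Supports `print`, `coef` and `predict`.
#' @examples
#' act <- c(A = 0.1, B = 0.3, C = 0.5, D = 0.7, E = 0.9)
#' fit_biomarker(act, 2 * act + 1, pathway = "toy", target = "r")
#' @export
fit_biomarker <- function(activity, targets, pathway = "pathway",
                          target = c("r", "K"), grouping = "all") {
  target <- match.arg(target)
  common <- intersect(names(activity), names(targets))
  if (is.null(names(activity)) || is.null(names(targets))) {
    if (length(activity) != length(targets)) stop("length mismatch")
    common <- seq_along(activity)
  }
  x <- as.numeric(activity[common])
  y <- as.numeric(targets[common])
  n <- length(x)
  if (n < 3L) stop("at least 3 paired (cell line, value) observations required")

  degenerate <- stats::var(x) < .Machine$double.eps
  if (degenerate) {
    out <- list(pathway = pathway, target = target, grouping = grouping,
                slope = NA_real_, intercept = mean(y), pearson = NA_real_,
                r2 = NA_real_, adj_r2 = NA_real_, p_value = NA_real_,
                fdr = NA_real_, n = n, degenerate = TRUE)
    class(out) <- "biomarker_fit"
    return(out)
  }

  lmfit <- stats::lm(y ~ x)
  sm <- summary(lmfit)
  out <- list(pathway = pathway, target = target, grouping = grouping,
              slope = unname(stats::coef(lmfit)[2]),
              intercept = unname(stats::coef(lmfit)[1]),
              pearson = stats::cor(x, y),
              r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
              p_value = sm$coefficients[2, 4], fdr = NA_real_,
              n = n, degenerate = FALSE)
  class(out) <- "biomarker_fit"
  out
}

#' @export
print.biomarker_fit <- function(x, ...) {
  cat(sprintf("Biomarker model: %s ~ '%s' activity (%s cells)\n",
              x$target, x$pathway, x$grouping))
  if (x$degenerate) {
    cat("  degenerate: zero activity variance\n")
    return(invisible(x))
  }
  cat(sprintf("  slope a = %.4g, intercept c = %.4g  (n = %d)\n",
              x$slope, x$intercept, x$n))
  cat(sprintf("  Pearson = %.3f, adj-R2 = %.3f, p = %.3g%s\n",
              x$pearson, x$adj_r2, x$p_value,
              if (is.na(x$fdr)) "" else sprintf(", FDR p = %.3g", x$fdr)))
  invisible(x)
}

#' @export
coef.biomarker_fit <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' Predict growth parameters from pathway activity
#'
#' Applies the fitted linear map `delta = a * p + c` to per-cell (or
#' per-clone) activity scores.
#'
#' @param object a non-degenerate [fit_biomarker()] model.
#' @param activity numeric vector of activity scores `p`.
#' @param ... unused.
#' @return predicted parameter values, named like `activity`.
#' @export
predict.biomarker_fit <- function(object, activity, ...) {
  if (object$degenerate) stop("cannot predict from a degenerate biomarker model")
  object$slope * activity + object$intercept
}

#' Rank biomarker models and keep the strongest
#'
#' Orders models for one target parameter by decreasing adjusted R-squared,
#' breaking ties by smaller p-value and then by pathway name; degenerate
#' models are dropped. The top `top_n` (default 5) are returned.
#'
#' @param models list of [fit_biomarker()] results sharing the same target.
#' @param top_n how many models to keep.
#' @return the top models, as a list, best first.
#' @export
rank_pathways <- function(models, top_n = 5) {
  models <- Filter(function(m) inherits(m, "biomarker_fit") && !m$degenerate,
                   models)
  if (length(models) == 0L) return(list())
  tg <- unique(vapply(models, function(m) m$target, ""))
  if (length(tg) != 1L) stop("models must share the target parameter")
  r2 <- vapply(models, function(m) m$adj_r2, 0)
  p <- vapply(models, function(m) m$p_value, 0)
  nm <- vapply(models, function(m) paste(m$pathway, m$grouping), "")
  ord <- order(-r2, p, nm)
  models[ord][seq_len(min(top_n, length(models)))]
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment `p_(i) * m / i` with monotonicity enforcement, as in
#' `stats::p.adjust(method = "BH")`, which implements it.
#'
#' @param pvalues raw p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Validate top biomarker models on the full cell-line panel
#'
#' Refits each prioritized model using all cell lines (training plus
#' validation), applies Benjamini-Hochberg FDR correction across the tested
#' models within each target parameter, and confirms models with adjusted
#' p < `fdr_level`.
#'
#' @param top_models list of [fit_biomarker()] models from the training
#'   ranking (may mix `r` and `K` targets; correction is per target).
#' @param medians_by_grouping named list, one cell-lines-by-pathways medians
#'   matrix per grouping (`"all"`, `"G0G1"`, `"S"`, `"G2M"`), covering all
#'   cell lines.
#' @param targets named list with numeric vectors `r` and `K` of fitted
#'   growth parameters for all cell lines.
#' @param fdr_level confirmation threshold on the adjusted p-value.
#' @return list with `models` (refitted, with `fdr` filled in) and
#'   `confirmed` (the subset with `fdr < fdr_level`).
#' @export
validate_biomarkers <- function(top_models, medians_by_grouping, targets,
                                fdr_level = 0.05) {
  if (length(top_models) == 0L) {
    return(list(models = list(), confirmed = list()))
  }
  refits <- list()
  for (m in top_models) {
    med <- medians_by_grouping[[m$grouping]]
    if (is.null(med) || !(m$pathway %in% colnames(med))) {
      warning("no activity medians for ", m$pathway, " / ", m$grouping,
              "; model skipped")
      next
    }
    tg <- targets[[m$target]]
    lines <- intersect(rownames(med), names(tg))
    if (length(lines) < 3L) {
      warning("missing cell-line targets for ", m$pathway, "; model skipped")
      next
    }
    refits[[length(refits) + 1L]] <-
      fit_biomarker(stats::setNames(med[lines, m$pathway], lines), tg[lines],
                    pathway = m$pathway, target = m$target,
                    grouping = m$grouping)
  }
  if (length(refits) == 0L) return(list(models = list(), confirmed = list()))
  for (tg in unique(vapply(refits, function(m) m$target, ""))) {
    idx <- which(vapply(refits, function(m) m$target, "") == tg)
    adj <- bh_fdr(vapply(refits[idx], function(m) m$p_value, 0))
    for (i in seq_along(idx)) refits[[idx[i]]]$fdr <- adj[i]
  }
  confirmed <- Filter(function(m) !is.na(m$fdr) && m$fdr < fdr_level, refits)
  list(models = refits, confirmed = confirmed)
}

#' Summarize biomarker models as a table
#'
#' @param models list of [fit_biomarker()] results.
#' @return data frame with one row per model (pathway, grouping, target,
#'   slope, intercept, Pearson, adjusted R-squared, p, FDR p).
#' @export
biomarker_table <- function(models) {
  do.call(rbind, lapply(models, function(m) {
    data.frame(pathway = m$pathway, grouping = m$grouping, target = m$target,
               slope = m$slope, intercept = m$intercept, pearson = m$pearson,
               adj_r2 = m$adj_r2, p_value = m$p_value, fdr = m$fdr,
               degenerate = m$degenerate, stringsAsFactors = FALSE)
  }))
}
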