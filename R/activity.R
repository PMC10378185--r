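#' Filter cells by detected-feature count
#'
#' Removes cells in which fewer than `min_features` genes are detected
#' (expression > 0); the boundary is inclusive, so a cell with exactly
#' `min_features` nonzero genes is kept.
#'
#' @param expr genes-by-cells numeric matrix (dense or `Matrix` sparse) with
#'   gene IDs as rownames and cell IDs as colnames; entries non-negative.
#' @param min_features minimum number of nonzero genes per cell (default
#'   200).
#' @return the expression matrix restricted to passing cells.
#' @export
filter_cells <- function(expr, min_features = 200) {
  check_expression(expr)
  nz <- if (inherits(expr, "sparseMatrix")) {
    Matrix::colSums(expr > 0)
  } else {
    colSums(expr > 0)
  }
  keep <- nz >= min_features
  if (!any(keep)) {
    stop("all cells removed: no cell has >= ", min_features,
         " detected features")
  }
  expr[, keep, drop = FALSE]
}

check_expression <- function(expr) {
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix needs gene rownames and cell colnames")
  }
  if (anyDuplicated(rownames(expr))) stop("duplicated gene IDs")
  if (anyDuplicated(colnames(expr))) stop("duplicated cell IDs")
  if (min(expr) < 0) stop("expression entries must be non-negative")
  invisible(expr)
}

#' Per-cell rank-based gene-set activity (area under the recovery curve)
#'
#' Scores each cell for each gene set with the rank-AUC statistic: genes are
#' ranked by decreasing expression within the cell, and the recovery curve
#' counts how many gene-set members appear among the top `x` genes for
#' `x = 1 .. ceiling(top_fraction * G)` (default top 5% of all genes in the
#' matrix). The score is the area under this curve divided by the area of
#' the ideal curve for the same set size and threshold, so it lies in
#' `[0, 1]`, equals 1 when all members occupy the top ranks, and 0 when no
#' member is in the top fraction. Being rank-based, the score is invariant
#' to any monotone transform of a cell's expression values (depth
#' normalization, log transforms, unit changes).
#'
#' Ties in expression (ubiquitous in counts) are broken by a random
#' permutation drawn once per cell from `seed`, making scores deterministic
#' for a fixed seed.
#'
#' @param expr genes-by-cells matrix (see [filter_cells()]).
#' @param gene_sets named list of character vectors of gene IDs; members
#'   absent from the matrix are ignored (a set with no member present scores
#'   0 with a warning).
#' @param top_fraction fraction of top-ranked genes considered active
#'   (default 0.05).
#' @param seed tie-breaking seed (default 42).
#' @return a cells-by-gene-sets numeric matrix of scores in `[0, 1]`.
#' @examples
#' expr <- matrix(rpois(600, 2), nrow = 60,
#'                dimnames = list(paste0("g", 1:60), paste0("c", 1:10)))
#' aucell_scores(expr, list(set1 = c("g1", "g2", "g3")), top_fraction = 0.1)
#' @export
aucell_scores <- function(expr, gene_sets, top_fraction = 0.05, seed = 42) {
  check_expression(expr)
  if (is.null(names(gene_sets)) || any(!nzchar(names(gene_sets)))) {
    stop("`gene_sets` must be a named list")
  }
  if (top_fraction <= 0 || top_fraction > 1) stop("`top_fraction` in (0, 1]")
  genes <- rownames(expr)
  G <- length(genes)
  n_top <- as.integer(ceiling(top_fraction * G))
  cells <- colnames(expr)

  member_idx <- lapply(gene_sets, function(s) {
    idx <- which(genes %in% s)
    if (length(idx) == 0L) {
      warning("gene set has no members in the matrix; scores set to 0")
    }
    idx
  })
  # ideal area: all m members stacked at the top ranks
  ideal <- vapply(member_idx, function(idx) {
    m <- length(idx)
    if (m == 0L) return(1)  # avoid 0/0; scores are 0 anyway
    sum(pmin(seq_len(n_top), m))
  }, 0)

  scores <- matrix(0, nrow = length(cells), ncol = length(gene_sets),
                   dimnames = list(cells, names(gene_sets)))
  dense <- as.matrix(expr)
  # one tie-breaking permutation per cell, all drawn from one seeded stream
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  for (j in seq_along(cells)) {
    tiebreak <- sample.int(G)
    ranking <- order(-dense[, j], tiebreak)
    # rank position of each gene: pos[g] = rank of gene g in this cell
    pos <- integer(G)
    pos[ranking] <- seq_len(G)
    for (s in seq_along(member_idx)) {
      idx <- member_idx[[s]]
      if (length(idx) == 0L) next
      rk <- pos[idx]
      rk <- rk[rk <= n_top]
      # area under the step recovery curve evaluated at x = 1..n_top
      scores[j, s] <- sum(n_top - rk + 1L) / ideal[[s]]
    }
  }
  scores
}

#' Median gene-set activity per cell line and cell-cycle group
#'
#' Summarizes per-cell activity scores to one median per (cell line, gene
#' set), restricted to cells of a cell-cycle phase — `"G0G1"`, `"S"`,
#' `"G2M"` — or to `"all"` phases combined. Cell lines with no cell in the
#' requested group are absent from the output (with a warning).
#'
#' @param activity cells-by-gene-sets score matrix from [aucell_scores()].
#' @param annotations data frame with columns `cell_id`, `cell_line`,
#'   `clone_id`, `phase` (phases among `G0G1`, `S`, `G2M`).
#' @param grouping one of `"G0G1"`, `"S"`, `"G2M"`, `"all"`.
#' @return a cell-lines-by-gene-sets matrix of medians.
#' @export
median_activity_by_group <- function(activity, annotations,
                                     grouping = c("all", "G0G1", "S", "G2M")) {
  grouping <- match.arg(grouping)
  check_annotations(annotations)
  ann <- annotations[annotations$cell_id %in% rownames(activity), , drop = FALSE]
  if (grouping != "all") ann <- ann[ann$phase == grouping, , drop = FALSE]
  lines <- sort(unique(annotations$cell_line))
  present <- sort(unique(ann$cell_line))
  missing <- setdiff(lines, present)
  if (length(missing)) {
    warning("no cells in group '", grouping, "' for cell line(s): ",
            paste(missing, collapse = ", "))
  }
  out <- matrix(NA_real_, nrow = length(present), ncol = ncol(activity),
                dimnames = list(present, colnames(activity)))
  for (cl in present) {
    ids <- ann$cell_id[ann$cell_line == cl]
    out[cl, ] <- apply(activity[ids, , drop = FALSE], 2, stats::median)
  }
  out
}

check_annotations <- function(annotations) {
  need <- c("cell_id", "cell_line", "clone_id", "phase")
  if (!is.data.frame(annotations) || !all(need %in% names(annotations))) {
    stop("annotations need columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(annotations$phase), c("G0G1", "S", "G2M"))
  if (length(bad)) stop("unknown cell-cycle phase(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(annotations$cell_id)) stop("duplicated cell IDs in annotations")
  invisible(annotations)
}
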