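#' Read and write cell-count growth curves
#'
#' CSV with columns `time_days`, `count`, `population_id`; one file can hold
#' several populations.
#'
#' @param path CSV file path.
#' @return `read_growth_curves()`: a named list of [growth_curve()] objects,
#'   one per `population_id`.
#' @export
read_growth_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_days", "count", "population_id")
  if (!all(need %in% names(df))) {
    stop("'", path, "' must have columns: ", paste(need, collapse = ", "))
  }
  lapply(split(df, df$population_id), function(d) {
    d <- d[order(d$time_days), , drop = FALSE]
    growth_curve(d$time_days, d$count, d$population_id[1])
  })
}

#' @rdname read_growth_curves
#' @param curves a [growth_curve()] or list of them.
#' @export
write_growth_curves <- function(curves, path) {
  if (inherits(curves, "growth_curve")) curves <- list(curves)
  df <- do.call(rbind, lapply(curves, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a single-cell expression matrix
#'
#' Either MatrixMarket (`.mtx` with `*_genes.tsv` / `*_barcodes.tsv`
#' sidecars, genes in rows) or a dense CSV with gene IDs in the first
#' column and cell IDs as header.
#'
#' @param path `.mtx` or `.csv` file.
#' @param genes_path,barcodes_path sidecar paths (default derived from
#'   `path` by replacing `.mtx` with `_genes.tsv` / `_barcodes.tsv`).
#' @return genes-by-cells matrix (sparse `dgCMatrix` for MTX input).
#' @export
read_expression <- function(path, genes_path = NULL, barcodes_path = NULL) {
  if (grepl("\\.mtx$", path)) {
    if (is.null(genes_path)) genes_path <- sub("\\.mtx$", "_genes.tsv", path)
    if (is.null(barcodes_path)) {
      barcodes_path <- sub("\\.mtx$", "_barcodes.tsv", path)
    }
    m <- methods::as(Matrix::readMM(path), "CsparseMatrix")
    rownames(m) <- readLines(genes_path)
    colnames(m) <- readLines(barcodes_path)
    m
  } else {
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    as.matrix(df)
  }
}

#' @rdname read_expression
#' @param expr genes-by-cells matrix.
#' @export
write_expression_mtx <- function(expr, path) {
  check_expression(expr)
  Matrix::writeMM(methods::as(Matrix::Matrix(expr, sparse = TRUE),
                              "generalMatrix"), path)
  writeLines(rownames(expr), sub("\\.mtx$", "_genes.tsv", path))
  writeLines(colnames(expr), sub("\\.mtx$", "_barcodes.tsv", path))
  invisible(path)
}

#' Read and write gene sets in GMT format
#'
#' One set per line: name, description, then member gene IDs,
#' tab-separated.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 60))
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, "", USE.NAMES = FALSE)
  out
}

#' @rdname read_gmt
#' @param gene_sets named list of character vectors.
#' @export
write_gmt <- function(gene_sets, path) {
  writeLines(vapply(names(gene_sets), function(nm) {
    paste(c(nm, nm, gene_sets[[nm]]), collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Read and write cell annotations
#'
#' TSV with header `cell_id`, `cell_line`, `clone_id`, `phase`.
#'
#' @param path TSV file.
#' @return annotation data frame.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("annotation file '", path, "' is empty")
  check_annotations(df)
  df
}

#' @rdname read_annotations
#' @param annotations annotation data frame.
#' @export
write_annotations <- function(annotations, path) {
  check_annotations(annotations)
  utils::write.table(annotations, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read and write a clone system as YAML
#'
#' YAML with fields `v` and `clones` (list of `id`, `r`, `K`, optional
#' `N0`).
#'
#' @param path YAML file.
#' @return a [clone_system()].
#' @export
read_clone_system <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$clones)) stop("'", path, "' has no `clones` entry")
  ids <- vapply(y$clones, function(c) as.character(c$id), "")
  state <- vapply(y$clones, function(c) {
    if (is.null(c$N0)) NA_real_ else as.numeric(c$N0)
  }, 0)
  clone_system(ids,
               r = vapply(y$clones, function(c) as.numeric(c$r), 0),
               K = vapply(y$clones, function(c) as.numeric(c$K), 0),
               v = if (is.null(y$v)) 1 else as.numeric(y$v),
               state = if (all(is.na(state))) NULL else state)
}

#' @rdname read_clone_system
#' @param system a [clone_system()].
#' @export
write_clone_system <- function(system, path) {
  stopifnot(inherits(system, "clone_system"))
  clones <- lapply(seq_along(system$clone_ids), function(i) {
    c(list(id = system$clone_ids[i], r = system$r[i], K = system$K[i]),
      if (!is.null(system$state)) list(N0 = system$state[i]))
  })
  yaml::write_yaml(list(v = system$v, clones = clones), path)
  invisible(path)
}
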