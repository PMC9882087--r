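#' Construct a feature-by-module weight matrix
#'
#' The projection basis of the pipeline: a sparse, non-negative matrix whose
#' rows are expression features (microarray probe sets or genes) and whose
#' columns are co-expression modules. Column labels conventionally carry a
#' trailing `+`/`-` marking the sign branch of the underlying independent
#' component; the labels are treated as opaque here.
#'
#' @param weights a matrix or [Matrix::sparseMatrix()] with unique, non-empty
#'   row names (feature ids) and column names (module ids); all entries must
#'   be non-negative and every column must contain at least one strictly
#'   positive weight.
#' @param level `"probe"` or `"gene"`: the feature namespace of the rows.
#' @return an object of class `module_matrix` wrapping a `dgCMatrix`.
#' @seealso [collapse_probes()], [discretize()], [read_module_matrix()]
#' @export
module_matrix <- function(weights, level = c("probe", "gene")) {
  level <- match.arg(level)
  w <- methods::as(methods::as(methods::as(weights, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  if (is.null(rownames(w)) || is.null(colnames(w))) {
    stop_modproj("module matrix needs feature (row) and module (column) names",
                 class = "modproj_invalid_matrix")
  }
  if (anyDuplicated(rownames(w)) || anyDuplicated(colnames(w))) {
    stop_modproj("feature ids and module ids must be unique",
                 class = "modproj_invalid_matrix")
  }
  if (any(w@x < 0)) {
    stop_modproj("module weights must be non-negative",
                 class = "modproj_invalid_matrix")
  }
  if (any(Matrix::colSums(w > 0) == 0)) {
    stop_modproj("every module column needs at least one positive weight",
                 class = "modproj_invalid_matrix")
  }
  structure(list(weights = w, level = level), class = "module_matrix")
}

#' @export
print.module_matrix <- function(x, ...) {
  w <- x$weights
  cat(sprintf("module_matrix: %d %s features x %d modules (%d nonzero weights)\n",
              nrow(w), x$level, ncol(w), length(w@x)))
  invisible(x)
}

#' @export
dim.module_matrix <- function(x) dim(x$weights)

#' Feature and module identifiers of a module matrix
#' @param x a `module_matrix`.
#' @return character vector of ids.
#' @export
feature_ids <- function(x) rownames(x$weights)

#' @rdname feature_ids
#' @export
module_ids <- function(x) colnames(x$weights)

#' Read / write a module matrix as triplet TSV
#'
#' The on-disk interchange format is a three-column tab-separated table
#' (`feature_id`, `module_id`, `weight`) listing the nonzero weights, plus an
#' alternative MatrixMarket route via [read_module_matrix_mtx()].
#'
#' @param path file path.
#' @param level feature namespace, `"probe"` or `"gene"`.
#' @return `read_module_matrix()` returns a `module_matrix`;
#'   `write_module_matrix()` returns `path` invisibly.
#' @export
read_module_matrix <- function(path, level = c("probe", "gene")) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("feature_id", "module_id", "weight")
  if (!all(need %in% names(df))) {
    stop_modproj("triplet TSV must have columns feature_id, module_id, weight",
                 class = "modproj_format_error")
  }
  feats <- sort(unique(df$feature_id))
  mods <- sort(unique(df$module_id))
  w <- Matrix::sparseMatrix(
    i = match(df$feature_id, feats),
    j = match(df$module_id, mods),
    x = as.numeric(df$weight),
    dims = c(length(feats), length(mods)),
    dimnames = list(feats, mods)
  )
  module_matrix(w, level = match.arg(level))
}

#' @rdname read_module_matrix
#' @param x a `module_matrix`.
#' @export
write_module_matrix <- function(x, path) {
  w <- methods::as(x$weights, "TsparseMatrix")
  df <- data.frame(
    feature_id = rownames(w)[w@i + 1L],
    module_id = colnames(w)[w@j + 1L],
    weight = w@x,
    stringsAsFactors = FALSE
  )
  df <- df[order(df$module_id, df$feature_id), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_module_matrix
#' @param mtx_path MatrixMarket file of weights.
#' @param feature_path,module_path sidecar label files, one id per line, in
#'   the row/column order of the MTX file.
#' @export
read_module_matrix_mtx <- function(mtx_path, feature_path, module_path,
                                   level = c("probe", "gene")) {
  w <- methods::as(Matrix::readMM(mtx_path), "CsparseMatrix")
  feats <- readLines(feature_path)
  mods <- readLines(module_path)
  if (length(feats) != nrow(w) || length(mods) != ncol(w)) {
    stop_modproj("label sidecars do not match matrix dimensions",
                 class = "modproj_format_error")
  }
  dimnames(w) <- list(feats, mods)
  module_matrix(w, level = match.arg(level))
}

#' Read / write a probe-to-gene map
#'
#' A two-column TSV (`probe_id`, `gene_id`) describing the many-to-one
#' mapping from array probe sets to gene identifiers.
#'
#' @param path file path.
#' @return a named character vector mapping probe id to gene id.
#' @export
read_probe_map <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_id") %in% names(df))) {
    stop_modproj("probe map TSV must have columns probe_id, gene_id",
                 class = "modproj_format_error")
  }
  if (anyDuplicated(df$probe_id)) {
    stop_modproj("duplicate probe_id in probe map",
                 class = "modproj_integrity_error")
  }
  stats::setNames(df$gene_id, df$probe_id)
}

#' @rdname read_probe_map
#' @param map named character vector (names = probe ids, values = gene ids).
#' @export
write_probe_map <- function(map, path) {
  write.table(
    data.frame(probe_id = names(map), gene_id = unname(map)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
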