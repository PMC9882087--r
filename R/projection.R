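#' Collapse a probe-level module matrix to gene level
#'
#' Expression signatures derived from microarray compendia are indexed by
#' probe sets; fold-change vectors from RNA-seq are indexed by genes. Probes
#' mapping to the same gene are collapsed by taking, per module, the
#' arithmetic mean of their weights (zero weights included in the mean).
#' Non-negativity is preserved.
#'
#' @param matrix a probe-level [module_matrix()].
#' @param map named character vector, probe id -> gene id, covering every
#'   matrix feature.
#' @return a gene-level `module_matrix`.
#' @export
collapse_probes <- function(matrix, map) {
  stopifnot(inherits(matrix, "module_matrix"))
  if (matrix$level != "probe") {
    stop_modproj("matrix is already gene-level", class = "modproj_invalid_matrix")
  }
  probes <- feature_ids(matrix)
  missing <- setdiff(probes, names(map))
  if (length(missing)) {
    stop_modproj("probes missing from map: ",
                 paste(utils::head(missing, 5L), collapse = ", "),
                 if (length(missing) > 5L) sprintf(" (and %d more)", length(missing) - 5L),
                 class = "modproj_unmapped_probe")
  }
  genes <- sort(unique(unname(map[probes])))
  # Sparse averaging operator A (gene x probe): A[g, p] = 1 / (#probes of g).
  gidx <- match(map[probes], genes)
  sizes <- tabulate(gidx, nbins = length(genes))
  a <- Matrix::sparseMatrix(
    i = gidx, j = seq_along(probes), x = 1 / sizes[gidx],
    dims = c(length(genes), length(probes)),
    dimnames = list(genes, probes)
  )
  module_matrix(a %*% matrix$weights, level = "gene")
}

#' Restrict a module matrix and a fold-change vector to shared genes
#'
#' Before projection both objects are restricted to the gene ids they share,
#' in identical canonical (lexicographic) order.
#'
#' @param matrix a gene-level [module_matrix()].
#' @param vec a [fold_change()] vector.
#' @return list with the restricted `matrix`, the restricted `vec`, and
#'   `n_shared`.
#' @export
align_features <- function(matrix, vec) {
  stopifnot(inherits(matrix, "module_matrix"), inherits(vec, "fold_change"))
  shared <- sort(intersect(feature_ids(matrix), vec$gene_ids))
  if (!length(shared)) {
    stop_modproj("matrix and vector share no gene ids",
                 class = "modproj_empty_intersection")
  }
  w <- matrix$weights[shared, , drop = FALSE]
  mat <- structure(list(weights = w, level = matrix$level),
                   class = "module_matrix")  # bypass ctor: columns may go all-zero
  v <- vec$values[match(shared, vec$gene_ids)]
  out_vec <- fold_change(v, gene_ids = shared, label = vec$label,
                         standardized = FALSE)
  out_vec$standardized <- vec$standardized  # restriction does not re-standardize
  list(matrix = mat, vec = out_vec, n_shared = length(shared))
}

#' Scalar projection of a fold-change vector onto every module
#'
#' For module column `m`, the scalar projection is `s = (v . m) / ||m||_2`:
#' the signed length of the vector's component along the module direction.
#' Setting `normalize = FALSE` returns the raw dot product instead. Modules
#' whose restricted column is all zero get `NA` (flagged, never significant
#' downstream).
#'
#' @param vec a standardized [fold_change()] vector, feature-aligned with
#'   `matrix` (see [align_features()]).
#' @param matrix the aligned [module_matrix()].
#' @param normalize divide by the column L2 norm (default) or not.
#' @return named numeric vector of per-module scalars.
#' @export
project <- function(vec, matrix, normalize = TRUE) {
  stopifnot(inherits(vec, "fold_change"), inherits(matrix, "module_matrix"))
  w <- matrix$weights
  if (length(vec$values) != nrow(w) || !identical(vec$gene_ids, rownames(w))) {
    stop_modproj("vector and matrix are not feature-aligned",
                 class = "modproj_shape_mismatch")
  }
  s <- as.numeric(Matrix::crossprod(w, vec$values))
  if (normalize) {
    norms <- sqrt(Matrix::colSums(w^2))
    s <- ifelse(norms > 0, s / norms, NA_real_)
  } else {
    s[Matrix::colSums(w != 0) == 0] <- NA_real_
  }
  stats::setNames(s, colnames(w))
}

#' Permutation null of the module projections
#'
#' The observed scalar for a module is compared with the scalars obtained
#' from random reassignments of gene labels to fold-change values. Each of
#' the `n_perm` permutations shuffles the vector's values over the shared
#' gene labels (permutations are drawn after feature restriction) and
#' projects the shuffled vector onto every module. Permutation r consumes
#' the r-th block of the seeded random stream, so the table is independent
#' of the module count and byte-identical across runs at a fixed seed.
#'
#' @inheritParams project
#' @param n_perm number of permutations (default 100; at least 2 so the
#'   null standard deviation is defined).
#' @param seed integer RNG seed.
#' @return `n_perm` x `n_modules` matrix of permutation scalars.
#' @export
permute_project <- function(vec, matrix, n_perm = 100L, seed = 1L,
                            normalize = TRUE) {
  n_perm <- assert_count(n_perm, "n_perm")
  if (n_perm < 2L) {
    stop_modproj("n_perm must be >= 2 (null sd undefined otherwise)",
                 class = "modproj_invalid_threshold")
  }
  w <- matrix$weights
  if (length(vec$values) != nrow(w) || !identical(vec$gene_ids, rownames(w))) {
    stop_modproj("vector and matrix are not feature-aligned",
                 class = "modproj_shape_mismatch")
  }
  n <- length(vec$values)
  perms <- with_seed(seed, {
    vapply(seq_len(n_perm), function(r) sample.int(n), integer(n))
  })
  shuffled <- matrix(vec$values[perms], nrow = n)  # genes x n_perm
  s <- t(as.matrix(Matrix::crossprod(w, shuffled)))  # n_perm x modules
  if (normalize) {
    norms <- sqrt(Matrix::colSums(w^2))
    s <- sweep(s, 2L, norms, "/")
    s[, norms == 0] <- NA_real_
  } else {
    s[, Matrix::colSums(w != 0) == 0] <- NA_real_
  }
  dimnames(s) <- list(NULL, colnames(w))
  s
}

#' Score modules against their permutation null
#'
#' Per module, the permutation scalars give a null mean and sample standard
#' deviation; the Z-score is `(s - mean) / sd`. Two p-values are reported:
#' an empirical two-sided p with add-one correction,
#' `p_emp = (1 + #\{r : |s_r - mean| >= |s - mean|\}) / (n_perm + 1)`
#' (ties count as at least as extreme), and the normal approximation
#' `p_norm = 2 * pnorm(-|z|)`. A module is called significant when
#' `z >= +z_cut` or `z <= -z_cut` and the (empirical, by default) p-value is
#' `<= alpha`. Modules with zero null standard deviation are flagged
#' undefined and never significant.
#'
#' @param scalars named per-module scalars from [project()].
#' @param perm_table permutation table from [permute_project()] on the same
#'   aligned inputs.
#' @param z_cut absolute Z-score cutoff (default 3).
#' @param alpha p-value cutoff (default 0.05).
#' @param p_type which p-value feeds the significance rule.
#' @return a `projection_result`: data frame with one row per module and
#'   columns `module_id`, `scalar`, `perm_mean`, `perm_sd`, `z`, `p_emp`,
#'   `p_norm`, `significant`, plus metadata attributes (`n_perm`, `z_cut`,
#'   `alpha`, `p_type`).
#' @export
score_modules <- function(scalars, perm_table, z_cut = 3, alpha = 0.05,
                          p_type = c("empirical", "normal")) {
  p_type <- match.arg(p_type)
  if (!identical(names(scalars), colnames(perm_table))) {
    stop_modproj("scalars and permutation table disagree on modules",
                 class = "modproj_shape_mismatch")
  }
  n_perm <- nrow(perm_table)
  mu <- colMeans(perm_table)
  sigma <- apply(perm_table, 2L, sd)
  z <- ifelse(is.finite(sigma) & sigma > 0, (scalars - mu) / sigma, NA_real_)
  dev_obs <- abs(scalars - mu)
  p_emp <- vapply(seq_along(scalars), function(j) {
    if (!is.finite(scalars[j])) return(NA_real_)
    (1 + sum(abs(perm_table[, j] - mu[j]) >= dev_obs[j])) / (n_perm + 1)
  }, numeric(1))
  p_norm <- pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)  # underflow floor
  p_use <- if (p_type == "empirical") p_emp else p_norm
  significant <- !is.na(z) & abs(z) >= z_cut & !is.na(p_use) & p_use <= alpha
  res <- data.frame(
    module_id = names(scalars), scalar = unname(scalars),
    perm_mean = unname(mu), perm_sd = unname(sigma), z = unname(z),
    p_emp = unname(p_emp), p_norm = unname(p_norm),
    significant = significant, stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  structure(res, class = c("projection_result", "data.frame"),
            n_perm = n_perm, z_cut = z_cut, alpha = alpha, p_type = p_type)
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf(
    "projection_result: %d modules, %d significant (|z| >= %g, p_%s <= %g, %d permutations)\n",
    nrow(x), sum(x$significant), attr(x, "z_cut"),
    if (identical(attr(x, "p_type"), "empirical")) "emp" else "norm",
    attr(x, "alpha"), attr(x, "n_perm")))
  NextMethod()
}

#' Module ids called significant in a projection result
#' @param result a `projection_result`.
#' @return character vector of module ids.
#' @export
significant_modules <- function(result) {
  stopifnot(inherits(result, "projection_result"))
  result$module_id[result$significant]
}

#' Run the full module-projection pipeline on one comparison
#'
#' Composes the pipeline stages in order: collapse the matrix to gene level
#' (when probe-level and a map is supplied), center and scale the
#' fold-change vector, restrict matrix and vector to shared genes, project
#' onto every module, build the permutation null, and score. Provenance
#' (seed, permutation count, shared-feature count, comparison label) is
#' recorded on the result.
#'
#' @param vec a raw [fold_change()] vector (standardized internally), or a
#'   [dge_table()] whose `logFC` column is used.
#' @param matrix a [module_matrix()] at probe or gene level.
#' @param map probe-to-gene map, required when `matrix` is probe-level.
#' @param n_perm,seed,z_cut,alpha,normalize,p_type see the stage functions.
#' @return a `projection_result` with metadata attributes, including
#'   `n_shared_features`, `seed` and `comparison`.
#' @examples
#' sc <- synthetic_scenario(seed = 7, n_genes = 300, n_probes = 330,
#'                          n_modules = 20, nnz_per_module = 15,
#'                          planted = planted_signal("M_3+", beta = 8))
#' mat <- collapse_probes(gen_module_matrix(sc), gen_probe_map(sc))
#' res <- run_projection(gen_lfc(sc, mat), mat, seed = 7)
#' head(res[order(-abs(res$z)), ])
#' @export
run_projection <- function(vec, matrix, map = NULL, n_perm = 100L, seed = 1L,
                           z_cut = 3, alpha = 0.05, normalize = TRUE,
                           p_type = c("empirical", "normal")) {
  if (inherits(vec, "dge_table")) {
    vec <- fold_change(vec$logFC, gene_ids = vec$gene_id,
                       label = attr(vec, "label"))
  }
  stopifnot(inherits(vec, "fold_change"), inherits(matrix, "module_matrix"))
  if (matrix$level == "probe") {
    if (is.null(map)) {
      stop_modproj("probe-level matrix needs a probe-to-gene map",
                   class = "modproj_unmapped_probe")
    }
    matrix <- collapse_probes(matrix, map)
  }
  if (!vec$standardized) vec <- standardize(vec)
  al <- align_features(matrix, vec)
  scalars <- project(al$vec, al$matrix, normalize = normalize)
  perm <- permute_project(al$vec, al$matrix, n_perm = n_perm, seed = seed,
                          normalize = normalize)
  res <- score_modules(scalars, perm, z_cut = z_cut, alpha = alpha,
                       p_type = p_type)
  attr(res, "seed") <- as.integer(seed)
  attr(res, "n_shared_features") <- al$n_shared
  attr(res, "comparison") <- vec$label
  res
}

#' Write a projection result as TSV plus a run-metadata JSON
#'
#' @param result a `projection_result` from [run_projection()].
#' @param path output TSV path; metadata goes to `paste0(path, ".json")`.
#' @return invisibly, the TSV path.
#' @export
write_projection_result <- function(result, path) {
  stopifnot(inherits(result, "projection_result"))
  write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta <- list(
    comparison = attr(result, "comparison"),
    n_perm = attr(result, "n_perm"),
    seed = attr(result, "seed"),
    n_shared_features = attr(result, "n_shared_features"),
    z_cut = attr(result, "z_cut"),
    alpha = attr(result, "alpha"),
    p_type = attr(result, "p_type"),
    n_significant = sum(result$significant)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
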