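#' Z-score concordance between two projection results
#'
#' Compares the module Z-profiles of two comparisons (e.g. mutant-vs-wildtype
#' against mutant-vs-rescue at one stage): Pearson correlation of the (z_A,
#' z_B) pairs of in-scope modules, and the fraction of each result's
#' significant modules with positive Z.
#'
#' @param res_a,res_b `projection_result`s over the same module universe.
#' @param scope which modules enter the correlation: `"intersection"`
#'   (significant in both, default), `"union"` (significant in either),
#'   `"either"` (alias of union), or `"all"` (every module with defined Z in
#'   both — useful to describe null concordance when nothing is significant).
#' @return list of class `concordance_summary`: `labels`, `scope`,
#'   `n_modules_used`, `pearson_r` (NA when fewer than 2 modules are in
#'   scope), `frac_positive_a`, `frac_positive_b` (shares of each result's
#'   significant modules with z > 0; NA when none are significant).
#' @export
concordance <- function(res_a, res_b,
                        scope = c("intersection", "union", "either", "all")) {
  stopifnot(inherits(res_a, "projection_result"),
            inherits(res_b, "projection_result"))
  scope <- match.arg(scope)
  if (!setequal(res_a$module_id, res_b$module_id)) {
    stop_modproj("results cover different module universes",
                 class = "modproj_shape_mismatch")
  }
  b <- res_b[match(res_a$module_id, res_b$module_id), ]
  defined <- !is.na(res_a$z) & !is.na(b$z)
  in_scope <- switch(scope,
    intersection = defined & res_a$significant & b$significant,
    union = , either = defined & (res_a$significant | b$significant),
    all = defined
  )
  r <- if (sum(in_scope) >= 2L) cor(res_a$z[in_scope], b$z[in_scope]) else NA_real_
  frac_pos <- function(res) {
    sig <- res$significant & !is.na(res$z)
    if (!any(sig)) NA_real_ else mean(res$z[sig] > 0)
  }
  structure(
    list(labels = c(attr(res_a, "comparison"), attr(res_b, "comparison")),
         scope = scope, n_modules_used = sum(in_scope), pearson_r = r,
         frac_positive_a = frac_pos(res_a), frac_positive_b = frac_pos(b)),
    class = "concordance_summary"
  )
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf(
    "concordance (%s scope, %d modules): Pearson r = %s; frac positive = %s / %s\n",
    x$scope, x$n_modules_used, format(x$pearson_r, digits = 3),
    format(x$frac_positive_a, digits = 3),
    format(x$frac_positive_b, digits = 3)))
  invisible(x)
}

#' Modules significant in every one of several projection results
#'
#' The intersection filters out comparison-specific hits and retains the
#' co-expression signatures conserved across all supplied comparisons (e.g.
#' across larval, pupal and adult stages).
#'
#' @param results list of `projection_result`s over a common module
#'   universe.
#' @return sorted character vector of module ids significant in every
#'   result.
#' @export
intersect_significant <- function(results) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1), "projection_result")))
  sort(Reduce(intersect, lapply(results, significant_modules)))
}

#' Per-gene report for one module across comparisons
#'
#' Lists the module's gene set (discretized at `weight_cut`, or the full
#' nonzero support with `support_only = TRUE`) with each gene's module
#' weight and its raw log fold change in every supplied comparison — the
#' table behind per-module logFC plots. Genes absent from a comparison are
#' reported as `NA`, never as zero.
#'
#' @param module_id module to report.
#' @param matrix a gene-level [module_matrix()].
#' @param vecs list of raw [fold_change()] vectors, one per comparison.
#' @param weight_cut discretization cutoff (default 3).
#' @param support_only use the nonzero support instead of the discretized
#'   set.
#' @return data frame with `gene_id`, `weight`, then one logFC column per
#'   comparison label, sorted by descending weight then gene id.
#' @export
module_report <- function(module_id, matrix, vecs, weight_cut = 3,
                          support_only = FALSE) {
  stopifnot(inherits(matrix, "module_matrix"),
            all(vapply(vecs, inherits, logical(1), "fold_change")))
  if (!module_id %in% module_ids(matrix)) {
    stop_modproj("unknown module: ", module_id,
                 class = "modproj_unknown_module")
  }
  col <- as.numeric(matrix$weights[, module_id])
  names(col) <- feature_ids(matrix)
  keep <- if (support_only) col > 0 else col >= weight_cut
  genes <- names(col)[keep]
  out <- data.frame(gene_id = genes, weight = unname(col[keep]),
                    stringsAsFactors = FALSE)
  labels <- vapply(vecs, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop_modproj("comparison labels must be unique",
                 class = "modproj_integrity_error")
  }
  for (k in seq_along(vecs)) {
    out[[labels[k]]] <- vecs[[k]]$values[match(genes, vecs[[k]]$gene_ids)]
  }
  out <- out[order(-out$weight, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
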