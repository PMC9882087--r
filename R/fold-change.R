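#' Construct a per-gene log fold-change vector
#'
#' One genotype-pair comparison's logFC profile, the quantity projected onto
#' the module matrix. Values are raw logFC until [standardize()] is applied.
#'
#' @param values numeric vector of logFC values, finite.
#' @param gene_ids character vector of unique gene ids, same length; taken
#'   from `names(values)` when omitted.
#' @param label comparison label, e.g. `"MvsW_larva"`.
#' @param standardized logical; `TRUE` only for vectors already centered to
#'   mean 0 and scaled to unit sample variance.
#' @return an object of class `fold_change`.
#' @export
fold_change <- function(values, gene_ids = names(values), label = "comparison",
                        standardized = FALSE) {
  if (is.null(gene_ids)) {
    stop_modproj("gene ids are required", class = "modproj_invalid_vector")
  }
  values <- as.numeric(values)
  if (length(values) != length(gene_ids)) {
    stop_modproj("values and gene_ids differ in length",
                 class = "modproj_invalid_vector")
  }
  if (anyDuplicated(gene_ids)) {
    stop_modproj("gene ids must be unique", class = "modproj_invalid_vector")
  }
  if (!all(is.finite(values))) {
    stop_modproj("logFC values must be finite", class = "modproj_invalid_vector")
  }
  if (standardized) {
    if (abs(mean(values)) > 1e-10 || abs(sd(values) - 1) > 1e-10) {
      stop_modproj("standardized vector must have mean 0 and sd 1",
                   class = "modproj_invalid_vector")
    }
  }
  structure(
    list(label = label, gene_ids = as.character(gene_ids), values = values,
         standardized = isTRUE(standardized)),
    class = "fold_change"
  )
}

#' @export
print.fold_change <- function(x, ...) {
  cat(sprintf("fold_change '%s': %d genes%s\n", x$label, length(x$values),
              if (x$standardized) " (standardized)" else ""))
  invisible(x)
}

#' @export
length.fold_change <- function(x) length(x$values)

#' Center and scale a fold-change vector
#'
#' Before projection, each comparison's logFC vector is mean-0 centered and
#' scaled to unit variance (sample standard deviation, denominator n - 1),
#' so projections are comparable across comparisons regardless of the
#' overall amplitude of expression change.
#'
#' @param vec a [fold_change()] vector with at least two genes.
#' @return the standardized `fold_change`; idempotent on already-standardized
#'   input.
#' @export
standardize <- function(vec) {
  stopifnot(inherits(vec, "fold_change"))
  if (length(vec$values) < 2L) {
    stop_modproj("standardization needs at least 2 genes",
                 class = "modproj_degenerate_input")
  }
  s <- sd(vec$values)
  if (!is.finite(s) || s == 0) {
    stop_modproj("constant vector cannot be standardized",
                 class = "modproj_degenerate_input")
  }
  fold_change((vec$values - mean(vec$values)) / s,
              gene_ids = vec$gene_ids, label = vec$label, standardized = TRUE)
}

#' Read / write a fold-change vector as TSV
#'
#' Two columns: `gene_id` and `logFC`.
#'
#' @param path file path.
#' @param label comparison label for the returned object.
#' @return `read_fold_change()` returns a `fold_change`.
#' @export
read_fold_change <- function(path, label = basename(path)) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "logFC") %in% names(df))) {
    stop_modproj("logFC TSV must have columns gene_id, logFC",
                 class = "modproj_format_error")
  }
  fold_change(df$logFC, gene_ids = df$gene_id, label = label)
}

#' @rdname read_fold_change
#' @param vec a `fold_change`.
#' @export
write_fold_change <- function(vec, path) {
  write.table(
    data.frame(gene_id = vec$gene_ids, logFC = vec$values),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
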