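#' Construct a gene set
#'
#' @param set_id unique identifier.
#' @param genes character vector of member gene ids.
#' @param name human-readable name (defaults to `set_id`).
#' @param source `"module_discretization"` or `"annotation"`. Annotation
#'   sets must be nonempty; discretized sets may be empty (flagged via
#'   `is_empty`).
#' @return a list of class `gene_set`.
#' @export
gene_set <- function(set_id, genes, name = set_id,
                     source = c("annotation", "module_discretization")) {
  source <- match.arg(source)
  genes <- unique(as.character(genes))
  if (source == "annotation" && !length(genes)) {
    stop_modproj("annotation gene sets must be nonempty",
                 class = "modproj_invalid_set")
  }
  structure(list(set_id = set_id, name = name, genes = genes,
                 source = source, is_empty = !length(genes)),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s' (%s): %d genes%s\n", x$set_id, x$source,
              length(x$genes), if (x$is_empty) " [empty]" else ""))
  invisible(x)
}

#' Discretize a module matrix into gene sets
#'
#' A module's gene set is the features whose weight reaches `weight_cut`
#' (inclusive) in that column — the "most heavily weighted" members of the
#' co-expression signature. Sets shrink monotonically as the cutoff rises;
#' modules whose column maximum falls below the cutoff yield empty sets,
#' flagged but not fatal.
#'
#' @param matrix a [module_matrix()].
#' @param weight_cut weight threshold (default 3).
#' @return named list of [gene_set()] objects, one per module, with source
#'   `"module_discretization"`.
#' @export
discretize <- function(matrix, weight_cut = 3) {
  stopifnot(inherits(matrix, "module_matrix"))
  w <- matrix$weights
  feats <- rownames(w)
  out <- lapply(colnames(w), function(m) {
    col <- w[, m]
    gene_set(m, feats[as.numeric(col) >= weight_cut],
             source = "module_discretization")
  })
  stats::setNames(out, colnames(w))
}

#' Read / write gene sets in GMT format
#'
#' One set per line: `set_id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file path.
#' @param source source tag for the returned sets.
#' @return `read_gmt()` returns a named list of [gene_set()]s.
#' @export
read_gmt <- function(path, source = "annotation") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) {
      stop_modproj("GMT line needs id, description and at least one gene: ",
                   substr(ln, 1L, 40L),
                   class = "modproj_format_error")
    }
    gene_set(parts[1L], parts[-(1:2)], name = parts[2L], source = source)
  })
  stats::setNames(out, vapply(out, `[[`, character(1), "set_id"))
}

#' @rdname read_gmt
#' @param sets named list of `gene_set`s.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$set_id, s$name, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
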