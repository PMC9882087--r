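#' Construct a differential-gene-expression result table
#'
#' Holds one genotype-pair comparison's edgeR-style results: per gene, the
#' log fold change, average expression (logCPM), raw p-value and
#' Benjamini-Hochberg adjusted p-value (FDR).
#'
#' @param df data frame with columns `gene_id`, `logFC`, `logCPM`, `PValue`,
#'   `FDR`; gene ids unique, p-values in \[0, 1\], all numerics finite.
#' @param label comparison label, e.g. `"MvsW_larva"`.
#' @return a data frame of class `dge_table` with a `label` attribute.
#' @export
dge_table <- function(df, label = "comparison") {
  need <- c("gene_id", "logFC", "logCPM", "PValue", "FDR")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_modproj("missing column(s): ", paste(miss, collapse = ", "),
                 class = "modproj_format_error")
  }
  df <- df[, need]
  if (anyDuplicated(df$gene_id)) {
    stop_modproj("duplicate gene_id in DGE table",
                 class = "modproj_integrity_error")
  }
  num <- c("logFC", "logCPM", "PValue", "FDR")
  if (!all(vapply(df[num], function(v) all(is.finite(v)), logical(1)))) {
    stop_modproj("non-finite numeric values in DGE table",
                 class = "modproj_integrity_error")
  }
  if (any(df$PValue < 0 | df$PValue > 1) || any(df$FDR < 0 | df$FDR > 1)) {
    stop_modproj("p-values must lie in [0, 1]", class = "modproj_integrity_error")
  }
  structure(df, class = c("dge_table", "data.frame"), label = label)
}

# Header aliases accepted when reading foreign tables (case-insensitive).
.dge_aliases <- list(
  gene_id = c("gene_id", "gene", "genes", "geneid", "fbgn", "id"),
  logFC = c("logfc", "log_fc", "log2foldchange", "lfc"),
  logCPM = c("logcpm", "log_cpm", "aveexpr", "basemean"),
  PValue = c("pvalue", "p_value", "p.value", "pval"),
  FDR = c("fdr", "adj_p", "padj", "adj.p.val", "qvalue")
)

#' Read a DGE result table from TSV
#'
#' Expects an edgeR-dialect header (`gene_id`, `logFC`, `logCPM`, `PValue`,
#' `FDR`); common case-insensitive aliases such as `padj` or `adj.P.Val`
#' are accepted. Malformed files fail with an error naming the offending
#' column or row.
#'
#' @param path TSV file path.
#' @param label comparison label attached to the table.
#' @return a [dge_table()].
#' @export
read_dge_table <- function(path, label = basename(path)) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  lower <- tolower(names(df))
  out <- list()
  for (canon in names(.dge_aliases)) {
    hit <- which(lower %in% .dge_aliases[[canon]])
    if (!length(hit)) {
      stop_modproj("missing required column '", canon, "' in ", path,
                   class = "modproj_format_error")
    }
    out[[canon]] <- df[[hit[1L]]]
  }
  for (canon in c("logFC", "logCPM", "PValue", "FDR")) {
    v <- suppressWarnings(as.numeric(out[[canon]]))
    bad <- which(is.na(v) & !is.na(out[[canon]]))
    if (length(bad)) {
      stop_modproj(sprintf("non-numeric value in column '%s', row %d", canon,
                           bad[1L]),
                   class = "modproj_parse_error")
    }
    out[[canon]] <- v
  }
  dge_table(as.data.frame(out, stringsAsFactors = FALSE), label = label)
}

#' @rdname read_dge_table
#' @param table a `dge_table`.
#' @export
write_dge_table <- function(table, path) {
  stopifnot(inherits(table, "dge_table"))
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Low-expression filtering by counts per million
#'
#' CPM for gene g in sample s is `counts[g, s] / lib_size[s] * 1e6`; a gene
#' is retained when its CPM reaches `threshold` in at least `min_samples`
#' samples. The default `min_samples` should normally match the smallest
#' group size of the design (four replicates per group in the study layout
#' this emulates).
#'
#' @param counts gene-by-sample matrix of non-negative counts with row
#'   names.
#' @param threshold CPM cutoff (default 1, i.e. drop genes with CPM < 1).
#' @param min_samples number of samples that must reach the cutoff.
#' @param lib_sizes per-sample library sizes; column sums by default.
#' @return character vector of retained gene ids.
#' @export
filter_by_cpm <- function(counts, threshold = 1, min_samples = 4L,
                          lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    stop_modproj("counts need gene row names", class = "modproj_format_error")
  }
  if (any(counts < 0)) {
    stop_modproj("counts must be non-negative", class = "modproj_integrity_error")
  }
  if (any(lib_sizes <= 0)) {
    stop_modproj("library sizes must be positive", class = "modproj_integrity_error")
  }
  min_samples <- assert_count(min_samples, "min_samples")
  cpm <- sweep(counts, 2L, lib_sizes, "/") * 1e6
  keep <- rowSums(cpm >= threshold) >= min_samples
  rownames(counts)[keep]
}

#' Call differentially expressed genes by threshold
#'
#' A gene is differentially expressed when `|logFC| >= lfc_cut` and its
#' adjusted p-value is `<= alpha`; both boundaries inclusive. The call is
#' split by direction of change.
#'
#' @param table a [dge_table()].
#' @param lfc_cut absolute log fold-change cutoff (default 0.5).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return an object of class `deg_partition`: list with `label`, disjoint
#'   gene-id sets `up` and `down`, and the thresholds used.
#' @export
call_deg <- function(table, lfc_cut = 0.5, alpha = 0.05) {
  stopifnot(inherits(table, "dge_table"))
  if (lfc_cut <= 0 || alpha <= 0) {
    stop_modproj("thresholds must be positive", class = "modproj_invalid_threshold")
  }
  sig <- table$FDR <= alpha
  structure(
    list(label = attr(table, "label"),
         up = table$gene_id[sig & table$logFC >= lfc_cut],
         down = table$gene_id[sig & table$logFC <= -lfc_cut],
         lfc_cut = lfc_cut, alpha = alpha),
    class = "deg_partition"
  )
}

#' @export
print.deg_partition <- function(x, ...) {
  cat(sprintf("deg_partition '%s': %d up, %d down (|logFC| >= %g, FDR <= %g)\n",
              x$label, length(x$up), length(x$down), x$lfc_cut, x$alpha))
  invisible(x)
}

#' All genes of a DEG partition (up and down combined)
#' @param partition a [call_deg()] result.
#' @return character vector of gene ids.
#' @export
deg_genes <- function(partition) {
  stopifnot(inherits(partition, "deg_partition"))
  union(partition$up, partition$down)
}

#' Venn-style overlap summary across DEG partitions
#'
#' Decomposes the union of the comparisons' DEG sets into disjoint Venn
#' regions and counts each, plus pairwise shared-gene counts. By default a
#' comparison's DEG set is direction-agnostic (up and down pooled, matching
#' the one-set-per-comparison Venn layout); `by_direction = TRUE` instead
#' treats each direction of each comparison as its own set.
#'
#' @param partitions list of [call_deg()] results (length >= 2).
#' @param by_direction split each comparison into up/down sets first.
#' @return list of class `overlap_summary` with elements `regions` (data
#'   frame: one row per nonempty Venn region, logical membership columns,
#'   `count`), `pairwise` (data frame `set_a`, `set_b`, `shared`), `n_union`.
#' @export
overlap_summary <- function(partitions, by_direction = FALSE) {
  stopifnot(length(partitions) >= 2L,
            all(vapply(partitions, inherits, logical(1), "deg_partition")))
  sets <- if (by_direction) {
    out <- list()
    for (p in partitions) {
      out[[paste0(p$label, ".up")]] <- p$up
      out[[paste0(p$label, ".down")]] <- p$down
    }
    out
  } else {
    stats::setNames(lapply(partitions, deg_genes),
                    vapply(partitions, `[[`, character(1), "label"))
  }
  if (anyDuplicated(names(sets))) {
    stop_modproj("comparison labels must be unique",
                 class = "modproj_integrity_error")
  }
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  key <- apply(member, 1L, paste, collapse = "|")
  counts <- table(key)
  pattern <- do.call(rbind, lapply(strsplit(names(counts), "|", fixed = TRUE),
                                   function(k) k == "TRUE"))
  regions <- as.data.frame(pattern)
  names(regions) <- names(sets)
  regions$count <- as.integer(counts)
  regions <- regions[order(-rowSums(pattern), regions$count), , drop = FALSE]
  rownames(regions) <- NULL
  pairs <- utils::combn(names(sets), 2L)
  pairwise <- data.frame(
    set_a = pairs[1L, ], set_b = pairs[2L, ],
    shared = apply(pairs, 2L, function(ab) {
      length(intersect(sets[[ab[1L]]], sets[[ab[2L]]]))
    }),
    stringsAsFactors = FALSE
  )
  structure(list(regions = regions, pairwise = pairwise,
                 n_union = length(universe)),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("overlap_summary over %d sets, union size %d\n",
              ncol(x$regions) - 1L, x$n_union))
  print(x$regions)
  invisible(x)
}
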