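#' One-sided over-representation test of a gene set in a query list
#'
#' Hypergeometric upper-tail test of the overlap k between a query gene list
#' (e.g. a comparison's DEGs) and a gene set, against a background universe:
#' `p = P(X >= k)` with `X ~ Hypergeometric(K, N - K, n)` where `K` is the
#' set size within the background, `n` the query size and `N` the background
#' size. `method = "ease"` applies the EASE correction, replacing k by
#' `max(k - 1, 0)` for a more conservative score.
#'
#' @param query gene ids of the query list (must lie within `background`).
#' @param background gene ids of the universe the query was drawn from.
#' @param set a [gene_set()].
#' @param method `"fisher"` (plain hypergeometric) or `"ease"`.
#' @param comparison_label,direction labels carried onto the result for
#'   network bookkeeping.
#' @return one-row data frame of class `enriched_set` with columns
#'   `set_id`, `comparison_label`, `direction`, `k`, `K`, `n`, `N`, `p`
#'   (`q` is added later by [adjust_bh()] across a batch).
#' @export
enrich_set <- function(query, background, set, method = c("fisher", "ease"),
                       comparison_label = "query", direction = "all") {
  method <- match.arg(method)
  stopifnot(inherits(set, "gene_set"))
  background <- unique(as.character(background))
  query <- unique(as.character(query))
  if (!length(background)) {
    stop_modproj("background universe is empty", class = "modproj_invalid_set")
  }
  if (length(setdiff(query, background))) {
    stop_modproj("query genes must be a subset of the background",
                 class = "modproj_invalid_set")
  }
  set_bg <- intersect(set$genes, background)
  k <- length(intersect(query, set_bg))
  K <- length(set_bg)
  n <- length(query)
  N <- length(background)
  k_eff <- if (method == "ease") max(k - 1L, 0L) else k
  p <- phyper(k_eff - 1L, K, N - K, n, lower.tail = FALSE)
  structure(
    data.frame(set_id = set$set_id, comparison_label = comparison_label,
               direction = direction, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE),
    class = c("enriched_set", "data.frame")
  )
}

#' Enrich many sets against one query, with BH-adjusted q-values
#'
#' @inheritParams enrich_set
#' @param sets named list of [gene_set()]s.
#' @return data frame with one row per set, columns as in [enrich_set()]
#'   plus `q` (BH across the batch).
#' @export
enrich_sets <- function(query, background, sets, method = c("fisher", "ease"),
                        comparison_label = "query", direction = "all") {
  rows <- lapply(sets, enrich_set, query = query, background = background,
                 method = method, comparison_label = comparison_label,
                 direction = direction)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$q <- adjust_bh(out$p)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, validating front to `stats::p.adjust(method = "BH")`: adjusted
#' values are monotone along the sorted p-values, bounded below by the raw
#' p, and mapped back to the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return vector of q-values, same order as `p`.
#' @export
adjust_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_modproj("p-values must lie in [0, 1]", class = "modproj_invalid_p")
  }
  p.adjust(p, method = "BH")
}

#' Overlap (Szymkiewicz-Simpson) coefficient between two gene sets
#'
#' `|a intersect b| / min(|a|, |b|)`: 1 whenever one set contains the
#' other, 0 when disjoint. The edge criterion of enrichment-map networks.
#'
#' @param a,b nonempty character vectors of gene ids.
#' @return a number in \[0, 1\]; symmetric in its arguments.
#' @export
overlap_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b)) {
    stop_modproj("overlap coefficient of an empty set is undefined",
                 class = "modproj_invalid_set")
  }
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Build a gene-set overlap network from enrichment results
#'
#' Enrichment-map style construction: a set becomes a node when it passes
#' `p <= p_cut` and `q <= q_cut` in at least one comparison (every
#' qualifying comparison/direction is recorded on the node); undirected
#' edges join node pairs whose gene sets have
#' [overlap_coefficient()] `>= overlap_cut`. All three cutoffs are
#' inclusive. No self-edges.
#'
#' @param enriched data frame of enrichment rows (from [enrich_sets()] or
#'   rbind-ed [enrich_set()]s with a `q` column) covering every candidate
#'   node, possibly over several comparisons.
#' @param sets named list of [gene_set()]s supplying node membership for
#'   edges.
#' @param p_cut,q_cut node filters (defaults 0.05, 0.1).
#' @param overlap_cut edge filter (default 0.6).
#' @return list of class `set_network`: `nodes` (data frame `set_id`,
#'   `n_comparisons`, `comparisons`, `best_p`, `best_q`), `edges` (data
#'   frame `set_a`, `set_b`, `overlap`), `memberships` (the qualifying
#'   enrichment rows), and the cutoffs used.
#' @export
build_network <- function(enriched, sets, p_cut = 0.05, q_cut = 0.1,
                          overlap_cut = 0.6) {
  need <- c("set_id", "comparison_label", "direction", "p", "q")
  miss <- setdiff(need, names(enriched))
  if (length(miss)) {
    stop_modproj("enrichment table missing column(s): ",
                 paste(miss, collapse = ", "),
                 class = "modproj_format_error")
  }
  pass <- enriched[enriched$p <= p_cut & enriched$q <= q_cut, , drop = FALSE]
  node_ids <- sort(unique(pass$set_id))
  absent <- setdiff(node_ids, names(sets))
  if (length(absent)) {
    stop_modproj("enriched set(s) missing from `sets`: ",
                 paste(absent, collapse = ", "),
                 class = "modproj_integrity_error")
  }
  nodes <- do.call(rbind, lapply(node_ids, function(id) {
    rows <- pass[pass$set_id == id, , drop = FALSE]
    data.frame(
      set_id = id,
      n_comparisons = length(unique(rows$comparison_label)),
      comparisons = paste(sort(unique(rows$comparison_label)), collapse = ","),
      best_p = min(rows$p), best_q = min(rows$q),
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(nodes)) {
    nodes <- data.frame(set_id = character(), n_comparisons = integer(),
                        comparisons = character(), best_p = numeric(),
                        best_q = numeric(), stringsAsFactors = FALSE)
  }
  edges <- data.frame(set_a = character(), set_b = character(),
                      overlap = numeric(), stringsAsFactors = FALSE)
  if (length(node_ids) >= 2L) {
    pairs <- utils::combn(node_ids, 2L)
    ov <- apply(pairs, 2L, function(ab) {
      overlap_coefficient(sets[[ab[1L]]]$genes, sets[[ab[2L]]]$genes)
    })
    keep <- ov >= overlap_cut
    edges <- data.frame(set_a = pairs[1L, keep], set_b = pairs[2L, keep],
                        overlap = ov[keep], stringsAsFactors = FALSE)
  }
  structure(
    list(nodes = nodes, edges = edges, memberships = pass,
         p_cut = p_cut, q_cut = q_cut, overlap_cut = overlap_cut),
    class = "set_network"
  )
}

#' @export
print.set_network <- function(x, ...) {
  cat(sprintf("set_network: %d nodes, %d edges (p <= %g, q <= %g, overlap >= %g)\n",
              nrow(x$nodes), nrow(x$edges), x$p_cut, x$q_cut, x$overlap_cut))
  invisible(x)
}

# igraph view of a set_network (isolated nodes included).
network_graph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes)
}

#' Recurrent ("hallmark") nodes of a set network
#'
#' Retains nodes enriched in at least `min_comparisons` distinct
#' comparisons — the criterion for gene sets that recur across genotype-pair
#' and stage contrasts rather than being specific to one. Also reports, per
#' connected component of the full network, how many of its nodes qualify.
#'
#' @param network a [build_network()] result.
#' @param min_comparisons minimum number of distinct comparisons (default
#'   4, as in a six-comparison design).
#' @return list of class `hallmark_summary`: `nodes` (qualifying rows of
#'   `network$nodes`) and `components` (data frame `component`, `n_nodes`,
#'   `n_hallmark`, `members`).
#' @export
hallmark_nodes <- function(network, min_comparisons = 4L) {
  stopifnot(inherits(network, "set_network"))
  min_comparisons <- assert_count(min_comparisons, "min_comparisons")
  keep <- network$nodes$n_comparisons >= min_comparisons
  comps <- data.frame(component = integer(), n_nodes = integer(),
                      n_hallmark = integer(), members = character(),
                      stringsAsFactors = FALSE)
  if (nrow(network$nodes)) {
    g <- network_graph(network)
    cc <- igraph::components(g)
    ids <- igraph::V(g)$name
    comps <- do.call(rbind, lapply(seq_len(cc$no), function(ci) {
      members <- ids[cc$membership == ci]
      data.frame(
        component = ci, n_nodes = length(members),
        n_hallmark = sum(members %in% network$nodes$set_id[keep]),
        members = paste(sort(members), collapse = ","),
        stringsAsFactors = FALSE
      )
    }))
  }
  structure(list(nodes = network$nodes[keep, , drop = FALSE],
                 components = comps, min_comparisons = min_comparisons),
            class = "hallmark_summary")
}

#' @export
print.hallmark_summary <- function(x, ...) {
  cat(sprintf("hallmark_summary: %d node(s) in >= %d comparisons\n",
              nrow(x$nodes), x$min_comparisons))
  invisible(x)
}

#' Write a set network as edge-list and node TSVs plus GraphML
#'
#' @param network a [build_network()] result.
#' @param prefix path prefix; writes `<prefix>_nodes.tsv`,
#'   `<prefix>_edges.tsv` and `<prefix>.graphml`.
#' @return invisibly, the named vector of paths written.
#' @export
write_network <- function(network, prefix) {
  stopifnot(inherits(network, "set_network"))
  paths <- c(nodes = paste0(prefix, "_nodes.tsv"),
             edges = paste0(prefix, "_edges.tsv"),
             graphml = paste0(prefix, ".graphml"))
  write.table(network$nodes, paths[["nodes"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(network$edges, paths[["edges"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  igraph::write_graph(network_graph(network), paths[["graphml"]],
                      format = "graphml")
  invisible(paths)
}
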