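# Brute-force reference implementations used as independent oracles.
# Each is a plain per-element loop, deliberately naive.

# Scalar projection, one module at a time, one gene at a time.
oracle_project <- function(values, weights, normalize = TRUE) {
  out <- numeric(ncol(weights))
  for (m in seq_len(ncol(weights))) {
    dot <- 0
    nrm2 <- 0
    for (g in seq_len(nrow(weights))) {
      dot <- dot + values[g] * weights[g, m]
      nrm2 <- nrm2 + weights[g, m]^2
    }
    out[m] <- if (normalize) {
      if (nrm2 > 0) dot / sqrt(nrm2) else NA_real_
    } else {
      if (all(weights[, m] == 0)) NA_real_ else dot
    }
  }
  names(out) <- colnames(weights)
  out
}

# Probe collapsing: per gene, per module, mean of probe weights.
oracle_collapse <- function(weights, map) {
  genes <- sort(unique(unname(map[rownames(weights)])))
  out <- matrix(0, length(genes), ncol(weights),
                dimnames = list(genes, colnames(weights)))
  for (g in genes) {
    probes <- names(map)[map == g & names(map) %in% rownames(weights)]
    for (m in seq_len(ncol(weights))) {
      out[g, m] <- mean(weights[probes, m])
    }
  }
  out
}

# CPM filter: per-gene loop over samples.
oracle_cpm_filter <- function(counts, threshold, min_samples,
                              lib_sizes = colSums(counts)) {
  keep <- character(0)
  for (g in rownames(counts)) {
    hits <- 0
    for (s in seq_len(ncol(counts))) {
      if (counts[g, s] / lib_sizes[s] * 1e6 >= threshold) hits <- hits + 1
    }
    if (hits >= min_samples) keep <- c(keep, g)
  }
  keep
}

# Venn regions by exhaustive per-gene membership enumeration.
oracle_venn <- function(sets) {
  universe <- sort(unique(unlist(sets)))
  keys <- character(0)
  for (g in universe) {
    keys <- c(keys, paste(vapply(sets, function(s) g %in% s, logical(1)),
                          collapse = "|"))
  }
  table(keys)
}

# BH step-up by hand: sort, p * n / rank, running min from the top.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# Hypergeometric tail by exhaustive enumeration of all n-subsets of 1..N.
oracle_fisher_enum <- function(N, n, K, k) {
  subsets <- utils::combn(N, n)
  hits <- 0
  for (j in seq_len(ncol(subsets))) {
    if (sum(subsets[, j] <= K) >= k) hits <- hits + 1
  }
  hits / ncol(subsets)
}

# All-pairs overlap-coefficient edges.
oracle_edges <- function(sets, cutoff) {
  ids <- sort(names(sets))
  out <- data.frame(set_a = character(), set_b = character(),
                    overlap = numeric(), stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i < j) {
        a <- sets[[ids[i]]]$genes
        b <- sets[[ids[j]]]$genes
        ov <- length(intersect(a, b)) / min(length(a), length(b))
        if (ov >= cutoff) {
          out <- rbind(out, data.frame(set_a = ids[i], set_b = ids[j],
                                       overlap = ov))
        }
      }
    }
  }
  out
}

# Small ready-made gene-level matrix for projection tests.
tiny_gene_matrix <- function(weights, genes = NULL, modules = NULL) {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(weights)))
  if (is.null(modules)) modules <- paste0("M_", seq_len(ncol(weights)), "+")
  dimnames(weights) <- list(genes, modules)
  module_matrix(weights, level = "gene")
}

tiny_dge <- function(logFC, FDR, PValue = FDR, label = "cmp") {
  dge_table(data.frame(
    gene_id = paste0("g", seq_along(logFC)), logFC = logFC,
    logCPM = rep(5, length(logFC)), PValue = pmin(PValue, FDR), FDR = FDR
  ), label = label)
}
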