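#' Describe a synthetic study scenario
#'
#' Parameters for the seeded generators that emulate the study's inputs at
#' desk scale: a sparse non-negative probe-by-module weight matrix, a
#' many-to-one probe-to-gene map, per-comparison log fold-change vectors
#' that are either pure noise or carry planted signals along chosen module
#' directions, and edgeR-style differential-expression tables.
#'
#' Nonzero module weights are drawn from a gamma distribution whose default
#' shape/scale (2, 1.5) places typical weights on both sides of the
#' discretization cutoff of 3, so weight thresholding is exercised
#' non-trivially. Planted signals use the L2-normalized module column as
#' direction, so `beta` equals the expected projection scalar of the
#' noise-free signal before standardization.
#'
#' @param seed integer seed governing matrix, map and noise structure.
#' @param n_genes number of genes.
#' @param n_probes number of probes (`>= n_genes`; surplus probes create the
#'   many-to-one structure that probe collapsing must resolve).
#' @param n_modules number of modules; labels follow the `M_k+`/`M_k-`
#'   paired-sign convention (labels are opaque, columns independent).
#' @param nnz_per_module strictly positive weights per module column.
#' @param weight_shape,weight_scale gamma parameters of nonzero weights.
#' @param planted planted module signals: a data frame with columns
#'   `module_id`, `beta`, `sign` (see [planted_signal()]), or an empty list
#'   for pure-noise vectors.
#' @param noise_sd standard deviation of per-gene logFC noise (> 0).
#' @param n_samples_per_group replicates per group for DGE-table emission.
#' @param dispersion per-gene noise scale used when simulating p-values.
#' @return a validated list of class `synthetic_scenario`.
#' @examples
#' sc <- synthetic_scenario(seed = 1, n_genes = 100, n_probes = 110,
#'                          n_modules = 10, nnz_per_module = 8)
#' mat <- gen_module_matrix(sc)
#' @export
synthetic_scenario <- function(seed = 1L,
                               n_genes = 2000L,
                               n_probes = n_genes,
                               n_modules = 200L,
                               nnz_per_module = 50L,
                               weight_shape = 2,
                               weight_scale = 1.5,
                               planted = list(),
                               noise_sd = 1,
                               n_samples_per_group = 4L,
                               dispersion = 0.5) {
  seed <- assert_count(seed, "seed", min = 0L)
  n_genes <- assert_count(n_genes, "n_genes")
  n_probes <- assert_count(n_probes, "n_probes")
  n_modules <- assert_count(n_modules, "n_modules")
  nnz_per_module <- assert_count(nnz_per_module, "nnz_per_module")
  n_samples_per_group <- assert_count(n_samples_per_group, "n_samples_per_group")
  if (n_probes < n_genes) {
    stop_modproj("n_probes must be >= n_genes",
                 class = "modproj_invalid_scenario")
  }
  if (nnz_per_module > n_genes) {
    stop_modproj("nnz_per_module cannot exceed n_genes",
                 class = "modproj_invalid_scenario")
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0 || !is.finite(noise_sd)) {
    stop_modproj("noise_sd must be positive and finite",
                 class = "modproj_invalid_scenario")
  }
  if (weight_shape <= 0 || weight_scale <= 0) {
    stop_modproj("gamma weight parameters must be positive",
                 class = "modproj_invalid_scenario")
  }
  if (is.data.frame(planted)) {
    stopifnot(all(c("module_id", "beta", "sign") %in% names(planted)))
  } else if (length(planted) == 0L) {
    planted <- data.frame(module_id = character(), beta = numeric(),
                          sign = numeric())
  } else {
    planted <- do.call(rbind, lapply(planted, as.data.frame))
  }
  if (nrow(planted)) {
    if (!all(is.finite(planted$beta))) {
      stop_modproj("planted effect sizes must be finite",
                   class = "modproj_invalid_scenario")
    }
    if (!all(planted$sign %in% c(-1, 1))) {
      stop_modproj("planted sign must be +1 or -1",
                   class = "modproj_invalid_scenario")
    }
    ids <- scenario_module_ids(n_modules)
    bad <- setdiff(planted$module_id, ids)
    if (length(bad)) {
      stop_modproj("planted module(s) not among scenario modules: ",
                   paste(bad, collapse = ", "),
                   class = "modproj_unknown_module")
    }
  }
  structure(
    list(seed = seed, n_genes = n_genes, n_probes = n_probes,
         n_modules = n_modules, nnz_per_module = nnz_per_module,
         weight_shape = weight_shape, weight_scale = weight_scale,
         planted = planted, noise_sd = noise_sd,
         n_samples_per_group = n_samples_per_group, dispersion = dispersion),
    class = "synthetic_scenario"
  )
}

#' @rdname synthetic_scenario
#' @param module_id module label the signal is planted along.
#' @param beta effect size (expected projection scalar of the clean signal).
#' @param sign +1 or -1.
#' @export
planted_signal <- function(module_id, beta, sign = 1) {
  data.frame(module_id = module_id, beta = beta, sign = sign,
             stringsAsFactors = FALSE)
}

# Module labels follow the paired +/- suffix convention: M_1+, M_1-, M_2+, ...
scenario_module_ids <- function(n_modules) {
  paste0("M_", ceiling(seq_len(n_modules) / 2),
         c("+", "-")[1L + (seq_len(n_modules) + 1L) %% 2L])
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(
    "synthetic_scenario: seed %d, %d genes / %d probes, %d modules (nnz %d), %d planted signal(s)\n",
    x$seed, x$n_genes, x$n_probes, x$n_modules, x$nnz_per_module,
    nrow(x$planted)))
  invisible(x)
}

#' Generate a sparse probe-by-module weight matrix
#'
#' Each module column receives exactly `nnz_per_module` strictly positive
#' gamma-distributed weights on a random probe subset; all other entries are
#' zero. Deterministic under the scenario seed.
#'
#' @param scenario a [synthetic_scenario()].
#' @return a probe-level [module_matrix()].
#' @export
gen_module_matrix <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (scenario$nnz_per_module > scenario$n_probes) {
    stop_modproj("nnz_per_module cannot exceed n_probes",
                 class = "modproj_invalid_scenario")
  }
  probes <- padded_ids("probe_", scenario$n_probes)
  mods <- scenario_module_ids(scenario$n_modules)
  nnz <- scenario$nnz_per_module
  with_seed(scenario$seed, {
    i <- unlist(lapply(seq_len(scenario$n_modules), function(j) {
      sort(sample.int(scenario$n_probes, nnz))
    }))
    x <- rgamma(nnz * scenario$n_modules, shape = scenario$weight_shape,
                scale = scenario$weight_scale)
    x <- pmax(x, .Machine$double.eps)  # keep strictly positive
    w <- Matrix::sparseMatrix(
      i = i, j = rep(seq_len(scenario$n_modules), each = nnz), x = x,
      dims = c(scenario$n_probes, scenario$n_modules),
      dimnames = list(probes, mods)
    )
    module_matrix(w, level = "probe")
  })
}

#' Generate a surjective probe-to-gene map
#'
#' The first `n_genes` probes are assigned one gene each (in shuffled order)
#' so the map is onto; each surplus probe is attached to a random gene,
#' creating the many-to-one structure that [collapse_probes()] resolves by
#' averaging.
#'
#' @param scenario a [synthetic_scenario()].
#' @return named character vector: probe id -> gene id.
#' @export
gen_probe_map <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  probes <- padded_ids("probe_", scenario$n_probes)
  genes <- padded_ids("gene_", scenario$n_genes)
  with_seed(scenario$seed + 1L, {
    assigned <- c(
      sample(genes),
      if (scenario$n_probes > scenario$n_genes) {
        genes[sample.int(scenario$n_genes,
                         scenario$n_probes - scenario$n_genes,
                         replace = TRUE)]
      }
    )
    stats::setNames(assigned, probes)
  })
}

# Clean (noise-free) planted signal on the gene universe of `matrix`.
planted_component <- function(scenario, matrix) {
  stopifnot(inherits(matrix, "module_matrix"))
  if (matrix$level != "gene") {
    stop_modproj("planted signals require a gene-level matrix; collapse probes first",
                 class = "modproj_invalid_matrix")
  }
  w <- matrix$weights
  signal <- numeric(nrow(w))
  pl <- scenario$planted
  if (nrow(pl)) {
    bad <- setdiff(pl$module_id, colnames(w))
    if (length(bad)) {
      stop_modproj("planted module(s) absent from matrix: ",
                   paste(bad, collapse = ", "),
                   class = "modproj_unknown_module")
    }
    for (k in seq_len(nrow(pl))) {
      col <- as.numeric(w[, pl$module_id[k]])
      signal <- signal + pl$beta[k] * pl$sign[k] * col / sqrt(sum(col^2))
    }
  }
  stats::setNames(signal, rownames(w))
}

#' Generate a log fold-change vector with optional planted module signals
#'
#' `logFC_g = sum_planted beta * sign * m_g / ||m||_2 + eps_g` with
#' `eps_g ~ N(0, noise_sd^2)`. With an empty planted list the vector is pure
#' noise. Deterministic under (`scenario`, `noise_seed`).
#'
#' @param scenario a [synthetic_scenario()].
#' @param matrix a gene-level [module_matrix()] (post [collapse_probes()]).
#' @param noise_seed seed for the noise draw; defaults to an offset of the
#'   scenario seed. [gen_paired()] varies only this.
#' @param label comparison label.
#' @return a raw (non-standardized) [fold_change()] vector.
#' @export
gen_lfc <- function(scenario, matrix, noise_seed = scenario$seed + 2L,
                    label = "synthetic") {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  signal <- planted_component(scenario, matrix)
  noise <- with_seed(noise_seed,
                     rnorm(length(signal), mean = 0, sd = scenario$noise_sd))
  fold_change(signal + noise, gene_ids = names(signal), label = label)
}

#' Generate a pair of comparisons sharing the planted signal
#'
#' Emulates two genotype-pair contrasts (e.g. mutant-vs-wildtype and
#' mutant-vs-rescue) that probe the same biology: both vectors carry the
#' identical planted component but independent noise realizations.
#'
#' @inheritParams gen_lfc
#' @return list of two [fold_change()] vectors (`a`, `b`).
#' @export
gen_paired <- function(scenario, matrix) {
  list(
    a = gen_lfc(scenario, matrix, noise_seed = scenario$seed + 3L, label = "pair_a"),
    b = gen_lfc(scenario, matrix, noise_seed = scenario$seed + 4L, label = "pair_b")
  )
}

#' Emit an edgeR-style differential-expression table for a fold-change vector
#'
#' Per gene, a standard error `se = dispersion / sqrt(n_samples_per_group)`,
#' a two-sided normal p-value for `logFC / se`, Benjamini-Hochberg FDR, and
#' a seeded logCPM column. Only the table shape and the ranking behavior are
#' modeled, not a count-level negative-binomial fit.
#'
#' @param vec a [fold_change()] vector.
#' @param scenario a [synthetic_scenario()] with `n_samples_per_group >= 2`.
#' @param label comparison label for the table.
#' @return a [dge_table()].
#' @export
gen_dge_table <- function(vec, scenario, label = vec$label) {
  stopifnot(inherits(vec, "fold_change"), inherits(scenario, "synthetic_scenario"))
  if (scenario$n_samples_per_group < 2L) {
    stop_modproj("n_samples_per_group must be >= 2",
                 class = "modproj_invalid_scenario")
  }
  se <- scenario$dispersion / sqrt(scenario$n_samples_per_group)
  z <- vec$values / se
  p <- 2 * pnorm(-abs(z))
  log_cpm <- with_seed(scenario$seed + 5L,
                       rnorm(length(vec$values), mean = 5, sd = 2))
  dge_table(
    data.frame(gene_id = vec$gene_ids, logFC = vec$values, logCPM = log_cpm,
               PValue = p, FDR = p.adjust(p, method = "BH"),
               stringsAsFactors = FALSE),
    label = label
  )
}

#' Write a full synthetic scenario to disk
#'
#' Emits the module matrix (triplet TSV), probe map TSV, logFC TSV, DGE
#' table TSV and a provenance JSON echoing seed and parameters — one
#' reproducible bundle per scenario.
#'
#' @param scenario a [synthetic_scenario()].
#' @param dir output directory (created if missing).
#' @return invisibly, the named list of file paths written.
#' @export
simulate_to_dir <- function(scenario, dir) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat <- gen_module_matrix(scenario)
  map <- gen_probe_map(scenario)
  gmat <- collapse_probes(mat, map)
  vec <- gen_lfc(scenario, gmat)
  tab <- gen_dge_table(vec, scenario)
  paths <- list(
    matrix = file.path(dir, "module_matrix.tsv"),
    probe_map = file.path(dir, "probe_map.tsv"),
    lfc = file.path(dir, "logfc.tsv"),
    dge = file.path(dir, "dge_table.tsv"),
    provenance = file.path(dir, "provenance.json")
  )
  write_module_matrix(mat, paths$matrix)
  write_probe_map(map, paths$probe_map)
  write_fold_change(vec, paths$lfc)
  write_dge_table(tab, paths$dge)
  prov <- unclass(scenario)
  prov$planted <- as.list(prov$planted)
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
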