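test_that("module matrix generation enforces sparsity, positivity and determinism", {
  sc <- synthetic_scenario(seed = 1, n_genes = 10, n_probes = 10,
                           n_modules = 2, nnz_per_module = 3)
  mat <- gen_module_matrix(sc)
  expect_s3_class(mat, "module_matrix")
  expect_equal(dim(mat), c(10L, 2L))
  expect_equal(unname(Matrix::colSums(mat$weights > 0)), c(3, 3))
  expect_true(all(mat$weights@x > 0))

  # boundary: nnz equal to n_probes fills the column
  sc_full <- synthetic_scenario(seed = 1, n_genes = 10, n_probes = 10,
                                n_modules = 2, nnz_per_module = 10)
  expect_true(all(as.matrix(gen_module_matrix(sc_full)$weights) > 0))

  # determinism: identical triplets on repeated calls
  mat2 <- gen_module_matrix(sc)
  expect_identical(as.matrix(mat$weights), as.matrix(mat2$weights))

  # module labels follow the paired +/- suffix convention
  expect_identical(module_ids(mat), c("M_1+", "M_1-"))
})

test_that("scenario validation rejects impossible configurations", {
  expect_error(synthetic_scenario(n_genes = 10, n_probes = 5),
               class = "modproj_invalid_scenario")
  expect_error(synthetic_scenario(n_genes = 10, nnz_per_module = 11),
               class = "modproj_invalid_scenario")
  expect_error(synthetic_scenario(noise_sd = 0),
               class = "modproj_invalid_scenario")
  expect_error(synthetic_scenario(n_modules = 4,
                                  planted = planted_signal("M_99+", 5)),
               class = "modproj_unknown_module")
  expect_error(synthetic_scenario(n_modules = 4,
                                  planted = planted_signal("M_1+", 5, sign = 2)),
               class = "modproj_invalid_scenario")
})

test_that("probe map is surjective, deterministic, and many-to-one when probes exceed genes", {
  sc_bij <- synthetic_scenario(seed = 2, n_genes = 5, n_probes = 5,
                               n_modules = 2, nnz_per_module = 2)
  map <- gen_probe_map(sc_bij)
  expect_length(map, 5)
  expect_equal(anyDuplicated(map), 0L)  # bijection

  sc6 <- synthetic_scenario(seed = 2, n_genes = 5, n_probes = 6,
                            n_modules = 2, nnz_per_module = 2)
  map6 <- gen_probe_map(sc6)
  expect_setequal(unique(unname(map6)), paste0("gene_", 1:5))  # surjective
  expect_equal(sum(table(map6) == 2), 1L)  # exactly one doubled gene

  expect_identical(gen_probe_map(sc6), map6)
})

test_that("generated logFC vectors carry planted signal plus gaussian noise", {
  # null vector: mean ~ 0, sd ~ noise_sd at n_genes = 5000
  sc <- synthetic_scenario(seed = 5, n_genes = 5000, n_probes = 5000,
                           n_modules = 10, nnz_per_module = 30, noise_sd = 0.7)
  g <- collapse_probes(gen_module_matrix(sc), gen_probe_map(sc))
  vec <- gen_lfc(sc, g)
  expect_lt(abs(mean(vec$values)), 4 * 0.7 / sqrt(5000))
  expect_lt(abs(sd(vec$values) - 0.7), 0.05)

  # noise-free limit: vector proportional to the normalized planted column
  sc_clean <- synthetic_scenario(seed = 5, n_genes = 200, n_probes = 200,
                                 n_modules = 4, nnz_per_module = 10,
                                 planted = planted_signal("M_1+", 5),
                                 noise_sd = 1e-9)
  g2 <- collapse_probes(gen_module_matrix(sc_clean), gen_probe_map(sc_clean))
  v2 <- gen_lfc(sc_clean, g2)
  col <- as.numeric(g2$weights[, "M_1+"])
  expect_equal(v2$values, 5 * col / sqrt(sum(col^2)), tolerance = 1e-6)

  # different noise seeds share the planted component exactly
  va <- gen_lfc(sc_clean, g2, noise_seed = 101)
  vb <- gen_lfc(sc_clean, g2, noise_seed = 102)
  expect_false(identical(va$values, vb$values))
  expect_equal(va$values - vb$values, rep(0, 200), tolerance = 1e-7)

  # planting an absent module fails
  sc_bad <- sc_clean
  sc_bad$planted <- planted_signal("M_77+", 5)
  expect_error(gen_lfc(sc_bad, g2), class = "modproj_unknown_module")
})

test_that("paired vectors share signal and correlate as noise dictates", {
  # planted = []: |r| small at n_genes = 5000
  sc0 <- synthetic_scenario(seed = 9, n_genes = 5000, n_probes = 5000,
                            n_modules = 10, nnz_per_module = 30)
  g0 <- collapse_probes(gen_module_matrix(sc0), gen_probe_map(sc0))
  pr0 <- gen_paired(sc0, g0)
  expect_lt(abs(cor(pr0$a$values, pr0$b$values)), 0.1)

  # strong shared signal: r > 0.9 (planted variance must dominate the noise)
  sc1 <- synthetic_scenario(seed = 9, n_genes = 300, n_probes = 300,
                            n_modules = 10, nnz_per_module = 30,
                            planted = rbind(planted_signal("M_2-", 10, -1),
                                            planted_signal("M_4+", 10),
                                            planted_signal("M_5+", 10)),
                            noise_sd = 0.2)
  g1 <- collapse_probes(gen_module_matrix(sc1), gen_probe_map(sc1))
  pr1 <- gen_paired(sc1, g1)
  expect_gt(cor(pr1$a$values, pr1$b$values), 0.9)

  # noise -> 0: the two vectors coincide
  sc2 <- sc1
  sc2$noise_sd <- 1e-12
  pr2 <- gen_paired(sc2, g1)
  expect_equal(pr2$a$values, pr2$b$values, tolerance = 1e-9)
})

test_that("emitted DGE tables have the edgeR shape and sound p-value behavior", {
  sc <- synthetic_scenario(seed = 4, n_genes = 400, n_probes = 400,
                           n_modules = 8, nnz_per_module = 20,
                           planted = planted_signal("M_1+", 12),
                           noise_sd = 0.1, dispersion = 0.5,
                           n_samples_per_group = 4)
  g <- collapse_probes(gen_module_matrix(sc), gen_probe_map(sc))
  vec <- gen_lfc(sc, g)
  vec$values[1] <- 0  # force an exactly-null gene
  tab <- gen_dge_table(vec, sc)
  expect_named(as.data.frame(tab),
               c("gene_id", "logFC", "logCPM", "PValue", "FDR"))
  expect_equal(tab$PValue[1], 1)          # logFC = 0 -> p = 1
  expect_true(all(tab$FDR >= tab$PValue)) # BH never decreases p

  # planted genes dominate the smallest-FDR ranks when beta >> dispersion
  planted_genes <- feature_ids(g)[as.numeric(g$weights[, "M_1+"]) > 0]
  top <- tab$gene_id[order(tab$FDR)][seq_along(planted_genes)]
  expect_gt(mean(top %in% planted_genes), 0.8)

  sc2 <- sc
  sc2$n_samples_per_group <- 1L
  expect_error(gen_dge_table(vec, sc2), class = "modproj_invalid_scenario")
})
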