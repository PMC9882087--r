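test_that("probe collapsing averages weights per gene and matches a loop oracle", {
  w <- matrix(c(2, 4, 0, 1, 3, 5), nrow = 3,
              dimnames = list(c("p1", "p2", "p3"), c("MA", "MB")))
  mat <- module_matrix(w, level = "probe")
  map <- c(p1 = "g", p2 = "g", p3 = "h")
  out <- collapse_probes(mat, map)
  expect_equal(out$level, "gene")
  expect_equal(as.numeric(out$weights["g", ]), c(3, 2))  # mean of 2,4 and 1,3
  expect_equal(as.numeric(out$weights["h", ]), c(0, 5))  # zeros enter the mean

  # one-to-one map: weights unchanged
  bij <- c(p1 = "a", p2 = "b", p3 = "c")
  out1 <- collapse_probes(mat, bij)
  expect_equal(unname(as.matrix(out1$weights)[order(c("a", "b", "c")), ]),
               unname(w))

  # random instances vs per-gene loop oracle
  withr::with_seed(3, {
    for (rep in 1:10) {
      wr <- matrix(round(runif(20 * 4, 0, 5), 2), 20, 4,
                   dimnames = list(paste0("p", 1:20), paste0("M", 1:4)))
      mr <- setNames(sample(paste0("g", 1:8), 20, replace = TRUE),
                     rownames(wr))
      got <- as.matrix(collapse_probes(module_matrix(wr, "probe"), mr)$weights)
      ref <- oracle_collapse(wr, mr)
      expect_equal(got[rownames(ref), ], ref, tolerance = 1e-12)
    }
  })

  expect_error(collapse_probes(mat, c(p1 = "g")),
               class = "modproj_unmapped_probe")
})

test_that("standardization centers and scales with sample sd and is idempotent", {
  v <- fold_change(c(1, -1), gene_ids = c("g1", "g2"))
  s <- standardize(v)
  expect_equal(s$values, c(0.70710678, -0.70710678), tolerance = 1e-8)
  expect_true(s$standardized)
  s2 <- standardize(s)
  expect_equal(s2$values, s$values, tolerance = 1e-12)
  expect_error(standardize(fold_change(c(5, 5, 5), paste0("g", 1:3))),
               class = "modproj_degenerate_input")
})

test_that("feature alignment restricts both objects to shared genes in canonical order", {
  mat <- tiny_gene_matrix(matrix(1, 5, 2), genes = paste0("g", 1:5))
  vec <- fold_change(3:7, gene_ids = paste0("g", 3:7))
  al <- align_features(mat, vec)
  expect_identical(feature_ids(al$matrix), c("g3", "g4", "g5"))
  expect_identical(al$vec$gene_ids, c("g3", "g4", "g5"))
  expect_equal(al$vec$values, c(3, 4, 5))
  expect_equal(al$n_shared, 3L)

  # identical universes: a reordering no-op
  vec_all <- fold_change(5:1, gene_ids = paste0("g", 5:1))
  al2 <- align_features(mat, vec_all)
  expect_equal(al2$vec$values, 1:5)

  expect_error(align_features(mat, fold_change(1:2, c("x1", "x2"))),
               class = "modproj_empty_intersection")
})

test_that("scalar projection matches hand values, a loop oracle, and its invariants", {
  m1 <- tiny_gene_matrix(matrix(c(1, 0, 0), 3, 1), genes = c("g1", "g2", "g3"))
  expect_equal(unname(project(fold_change(c(1, 0, 0), c("g1", "g2", "g3")), m1)), 1)

  m2 <- tiny_gene_matrix(matrix(c(3, 4), 2, 1), genes = c("g1", "g2"))
  v2 <- fold_change(c(1, 1), c("g1", "g2"))
  expect_equal(unname(project(v2, m2)), 1.4)             # (3+4)/5
  expect_equal(unname(project(v2, m2, normalize = FALSE)), 7)

  # orthogonal vector projects to zero
  expect_equal(unname(project(fold_change(c(4, -3), c("g1", "g2")), m2)), 0)

  withr::with_seed(8, {
    for (rep in 1:10) {
      n <- sample(5:200, 1); k <- sample(2:20, 1)
      w <- matrix(rbinom(n * k, 1, 0.3) * runif(n * k, 0, 6), n, k,
                  dimnames = list(paste0("g", seq_len(n)),
                                  paste0("M", seq_len(k))))
      v <- fold_change(rnorm(n), paste0("g", seq_len(n)))
      mat <- tiny_gene_matrix(w + 0, genes = rownames(w), modules = colnames(w))
      expect_equal(project(v, mat), oracle_project(v$values, w),
                   tolerance = 1e-10)
      # linearity
      a <- runif(1, 0.5, 3)
      va <- fold_change(a * v$values, v$gene_ids)
      expect_equal(unname(project(va, mat)), unname(a * project(v, mat)),
                   tolerance = 1e-10)
      # relabeling invariance: permute genes in both objects together
      perm <- sample(n)
      wp <- w[perm, , drop = FALSE]
      matp <- tiny_gene_matrix(wp + 0, genes = rownames(wp),
                               modules = colnames(wp))
      alp <- align_features(matp, v)
      expect_equal(project(alp$vec, alp$matrix), project(v, mat),
                   tolerance = 1e-10)
    }
  })
})

test_that("permutation nulls are seeded, shuffle shared labels only, and flag flat modules", {
  mat <- tiny_gene_matrix(cbind(flat = rep(2, 6), sparse = c(5, 0, 0, 3, 0, 0)),
                          genes = paste0("g", 1:6),
                          modules = c("flat", "sparse"))
  vec <- standardize(fold_change(c(3, -1, 2, 0, 1, -2), paste0("g", 1:6)))
  pt <- permute_project(vec, mat, n_perm = 50, seed = 4)
  expect_equal(dim(pt), c(50L, 2L))
  # equal weight on every gene: scalar invariant under permutation
  expect_equal(max(pt[, "flat"]) - min(pt[, "flat"]), 0, tolerance = 1e-12)
  # byte-identical under a fixed seed
  expect_identical(pt, permute_project(vec, mat, n_perm = 50, seed = 4))
  expect_false(identical(pt, permute_project(vec, mat, n_perm = 50, seed = 5)))
  # permuted rows are projections of permuted values
  expect_true(all(abs(sort(pt[1, "sparse"]) ) <= sum(abs(vec$values)) * 5))
  expect_error(permute_project(vec, mat, n_perm = 1, seed = 1),
               class = "modproj_invalid_threshold")

  # null mean of permutation scalars is ~0 for a standardized vector
  big <- tiny_gene_matrix(matrix(rbinom(500, 1, 0.1) * 4, 500, 1),
                          genes = paste0("g", 1:500))
  vb <- standardize(fold_change(rnorm(500), paste0("g", 1:500)))
  ptb <- permute_project(vb, big, n_perm = 200, seed = 2)
  expect_lt(abs(mean(ptb[, 1])), 3 * sd(ptb[, 1]) / sqrt(200))
})

test_that("module scoring yields correct z, empirical p, and the significance rule", {
  scalars <- c(M1 = 5, M2 = 0.1)
  pt <- cbind(M1 = c(rep(0.1, 49), -0.1), M2 = rnorm(50, 0, 0.05))
  res <- score_modules(scalars, pt, z_cut = 3, alpha = 0.05)
  expect_s3_class(res, "projection_result")
  expect_equal(res$z[1], (5 - mean(pt[, 1])) / sd(pt[, 1]))
  # p floor with add-one correction
  expect_equal(res$p_emp[1], 1 / 51)
  expect_true(res$significant[1])
  # p bounds
  expect_true(all(res$p_emp >= 1 / 51 & res$p_emp <= 1))
  expect_true(all(res$p_norm > 0 & res$p_norm <= 1))

  # observed scalar equal to the null mean: z = 0, not significant
  pt0 <- cbind(M = rnorm(100))
  res0 <- score_modules(c(M = mean(pt0)), pt0)
  expect_equal(res0$z, 0)
  expect_false(res0$significant)

  # zero null sd: flagged undefined, never significant
  ptc <- cbind(M = rep(2, 100))
  resc <- score_modules(c(M = 10), ptc)
  expect_true(is.na(resc$z))
  expect_false(resc$significant)

  # a strongly negative z is significant with its sign preserved
  ptn <- cbind(M = rnorm(100, 0, 1))
  resn <- score_modules(c(M = mean(ptn) - 4.9 * sd(ptn)), ptn)
  expect_lt(resn$z, -4.8)
  expect_true(resn$significant)
})

test_that("the composed pipeline recovers a planted module with the right sign", {
  sc <- synthetic_scenario(seed = 21, n_genes = 1000, n_probes = 1100,
                           n_modules = 50, nnz_per_module = 30,
                           planted = planted_signal("M_7-", 8, sign = -1),
                           noise_sd = 1)
  g <- collapse_probes(gen_module_matrix(sc), gen_probe_map(sc))
  res <- run_projection(gen_lfc(sc, g), g, n_perm = 100, seed = 99)
  top <- res$module_id[which.max(abs(res$z))]
  expect_equal(top, "M_7-")
  expect_lt(res$z[res$module_id == "M_7-"], 0)
  expect_true(res$significant[res$module_id == "M_7-"])
  expect_equal(attr(res, "n_shared_features"), 1000L)

  # identical seeded runs are identical; dge_table input route agrees
  res2 <- run_projection(gen_lfc(sc, g), g, n_perm = 100, seed = 99)
  expect_identical(as.data.frame(res), as.data.frame(res2))
  tab <- gen_dge_table(gen_lfc(sc, g), sc)
  res3 <- run_projection(tab, g, n_perm = 100, seed = 99)
  expect_equal(res3$z, res$z, tolerance = 1e-12)

  # probe-level matrix without a map is rejected
  expect_error(run_projection(gen_lfc(sc, g), gen_module_matrix(sc)),
               class = "modproj_unmapped_probe")
})
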