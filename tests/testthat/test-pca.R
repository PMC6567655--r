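# PCA engine: ranking, sample/gene PCA, scree, loadings, multifactor.

test_that("select_top_variable ranks by variance with stable ties", {
  tm <- toy_transformed(rbind(c(1, 1, 1), c(0, 2, 4), c(0, 1, 2)))
  expect_equal(select_top_variable(tm, 2), c("g2", "g3"))
  expect_equal(select_top_variable(tm, 10), c("g2", "g3", "g1"))

  const <- toy_transformed(matrix(5, 3, 3))
  expect_warning(top <- select_top_variable(const, 2), "zero")
  expect_equal(top, c("g1", "g2"))
})

test_that("sample PCA satisfies its algebraic identities", {
  tm <- toy_transformed(rbind(c(0, 1, 2, 3), c(5, 5, 5, 5), c(2, 2, 2, 2)))
  p <- pca_samples(tm, ntop = 3)
  expect_equal(p$variance_explained[1], 1)

  set.seed(3)
  tm2 <- toy_transformed(matrix(rnorm(24), nrow = 6))
  p2 <- pca_samples(tm2, ntop = 6)
  # reconstruction: scores * t(loadings) gives back the centered data
  # (columns in the variance-ranked order the PCA used)
  X <- t(tm2$values)[, p2$variable_ids]
  Xc <- scale(X, center = TRUE, scale = FALSE)
  expect_lt(max(abs(p2$scores %*% t(p2$loadings) - Xc)), 1e-8)
  # loadings orthonormal
  G <- crossprod(p2$loadings)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  # variance explained sums to 1, non-increasing
  expect_equal(sum(p2$variance_explained), 1, tolerance = 1e-8)
  expect_true(all(diff(p2$variance_explained) <= 1e-12))
  # matches the independent eigendecomposition oracle
  oracle <- eigen_pca_oracle(X)
  expect_equal(p2$variance_explained,
               oracle$variance_explained[seq_along(p2$variance_explained)],
               tolerance = 1e-8)
  expect_lt(max(abs(abs(p2$scores) - abs(oracle$scores[, 1:ncol(p2$scores)]))),
            1e-8)
  # deterministic sign convention
  for (k in seq_len(ncol(p2$loadings))) {
    expect_gte(p2$loadings[which.max(abs(p2$loadings[, k])), k], 0)
  }
})

test_that("permuting samples permutes scores and keeps variance explained", {
  set.seed(8)
  tm <- toy_transformed(matrix(rnorm(40), nrow = 8))
  p <- pca_samples(tm, ntop = 8)
  perm <- c(3, 1, 5, 2, 4)
  tm_p <- toy_transformed(tm$values[, perm],
                          samples = colnames(tm$values)[perm])
  p_p <- pca_samples(tm_p, ntop = 8)
  expect_equal(p_p$variance_explained, p$variance_explained, tolerance = 1e-10)
  expect_equal(p_p$scores, p$scores[perm, ], tolerance = 1e-8)
})

test_that("scree table accumulates variance explained", {
  p <- list(variance_explained = c(0.6, 0.3, 0.1))
  class(p) <- "pca_result"
  s <- scree(p)
  expect_equal(s$cumulative, c(0.6, 0.9, 1.0))
  expect_true(all(diff(s$cumulative) >= 0))

  p1 <- list(variance_explained = 1)
  class(p1) <- "pca_result"
  expect_equal(scree(p1)$cumulative, 1.0)
})

test_that("hi_loadings splits by sign and orders by magnitude", {
  p <- structure(list(
    loadings = matrix(c(0.9, -0.8, 0.1), ncol = 1,
                      dimnames = list(c("g1", "g2", "g3"), "PC1")),
    variable_ids = c("g1", "g2", "g3")
  ), class = "pca_result")
  h <- hi_loadings(p, 1, 1)
  expect_equal(h$positive$gene_id, "g1")
  expect_equal(h$negative$gene_id, "g2")

  h2 <- hi_loadings(p, 1, 5)
  expect_equal(h2$positive$gene_id, c("g1", "g3"))  # all of that sign
  expect_equal(h2$negative$gene_id, "g2")

  p_pos <- structure(list(
    loadings = matrix(c(0.9, 0.4), ncol = 1,
                      dimnames = list(c("g1", "g2"), "PC1")),
    variable_ids = c("g1", "g2")
  ), class = "pca_result")
  expect_equal(nrow(hi_loadings(p_pos, 1, 2)$negative), 0)
  expect_error(hi_loadings(p_pos, 3), "1\\.\\.1")
})

test_that("outlier removal recomputes the PCA on the reduced data", {
  set.seed(5)
  base <- matrix(rep(c(5, 8, 12), 4), nrow = 3) + rnorm(12, sd = 0.01)
  base[, 4] <- base[, 4] + 10
  tm <- toy_transformed(base)
  p_all <- pca_samples(tm, ntop = 3)
  expect_equal(pca_remove_samples(tm, character(0), ntop = 3)$scores,
               p_all$scores)
  p_red <- pca_remove_samples(tm, "s4", ntop = 3)
  expect_lt(p_red$variance_explained[1], p_all$variance_explained[1])
  expect_equal(length(p_red$observation_ids), 3)
  expect_error(pca_remove_samples(tm, "X", ntop = 3), "X")
  expect_error(pca_remove_samples(tm, c("s1", "s2", "s3"), ntop = 3),
               "fewer than 2")
})

test_that("gene PCA recovers planted clusters and biplot geometry", {
  world <- default_world()
  tg <- world$sim$truth$genes
  pg <- pca_genes(world$vst, ntop = 500)
  up <- intersect(tg$gene_id[tg$lfc > 0], pg$observation_ids)
  dn <- intersect(tg$gene_id[tg$lfc < 0], pg$observation_ids)
  s1 <- pg$scores[, 1]
  agree <- max(
    (sum(s1[up] > 0) + sum(s1[dn] < 0)) / (length(up) + length(dn)),
    (sum(s1[up] < 0) + sum(s1[dn] > 0)) / (length(up) + length(dn))
  )
  expect_gte(agree, 0.95)

  # a sample with high values in the up-cluster points toward it
  meta <- world$sim$bundle$metadata
  b_sample <- meta$sample_id[meta$condition == "B"][1]
  up_centroid <- colMeans(pg$scores[up, c(1, 2)])
  arrow <- pg$arrows[b_sample, c(1, 2)]
  expect_gt(sum(arrow * up_centroid), 0)

  # duplicated samples give coincident arrows
  m <- world$vst$values[, 1:4]
  m[, 4] <- m[, 3]
  colnames(m) <- paste0("s", 1:4)
  pg2 <- pca_genes(as_transformed(m), ntop = 100)
  expect_lt(max(abs(pg2$arrows["s3", ] - pg2$arrows["s4", ])), 1e-8)
})

test_that("rectangle selection is closed and ordered along PCx", {
  set.seed(2)
  tm <- toy_transformed(matrix(rnorm(50), nrow = 10))
  pg <- pca_genes(tm, ntop = 10)
  all_ids <- select_genes_in_box(pg, 1, 2, c(-Inf, Inf), c(-Inf, Inf))
  expect_setequal(all_ids, pg$observation_ids)
  expect_equal(all_ids, pg$observation_ids[order(pg$scores[, 1])])
  expect_equal(select_genes_in_box(pg, 1, 2, c(100, 101), c(100, 101)),
               character(0))
  g <- pg$observation_ids[1]
  pt <- pg$scores[g, 1:2]
  expect_equal(select_genes_in_box(pg, 1, 2, rep(pt[1], 2), rep(pt[2], 2)), g)
})

test_that("profile_data centers rows and preserves sample order", {
  tm <- toy_transformed(rbind(c(1, 2, 6), c(4, 4, 4)))
  pr <- profile_data(tm, c("g1", "g2"))
  expect_equal(names(pr), c("gene_id", "s1", "s2", "s3"))
  expect_lt(abs(sum(pr[1, -1])), 1e-10)
  expect_equal(as.numeric(pr[2, -1]), c(0, 0, 0))
  raw <- profile_data(tm, "g1", center = FALSE)
  expect_equal(as.numeric(raw[1, -1]), c(1, 2, 6))
  expect_error(profile_data(tm, "nope"), "nope")
})

test_that("multifactor PCA reduces to gene PCA for a single factor level", {
  set.seed(9)
  m <- matrix(rnorm(80), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
  meta <- tibble::tibble(sample_id = paste0("s", 1:8),
                         f1 = "A", f2 = rep(c("x", "y"), each = 4))
  pm <- pca_multifactor(as_transformed(m), meta, "f1", "f2", ntop = 10)
  ord <- c(paste0("s", 1:4), paste0("s", 5:8))  # f2-sorted = original here
  pg <- pca_genes(as_transformed(m[, ord]), ntop = 10)
  expect_equal(unname(pm$scores), unname(pg$scores), tolerance = 1e-8)
  expect_equal(sub("::.*", "", pm$observation_ids), pg$observation_ids)
})

test_that("multifactor PCA separates factor2-only genes from interactions", {
  sim <- simulate_counts(simulation_design(factor_levels = c(2, 2), seed = 42))
  sf <- estimate_size_factors(sim$bundle$counts)
  v <- vst(sim$bundle$counts, sf, fit_dispersion_trend(sim$bundle$counts, sf))
  pm <- pca_multifactor(v, sim$bundle$metadata, "condition", "batch", ntop = 500)
  tg <- sim$truth$genes
  pres <- unique(sub("::.*", "", pm$observation_ids))
  pair_dist <- function(gene) {
    rows <- paste(gene, c("A", "B"), sep = "::")
    sqrt(sum((pm$scores[rows[1], 1:2] - pm$scores[rows[2], 1:2])^2))
  }
  f2_genes <- intersect(tg$gene_id[tg$effect_type == "factor2"], pres)
  int_genes <- intersect(tg$gene_id[tg$effect_type == "interaction"], pres)
  d_f2 <- vapply(f2_genes, pair_dist, 1)
  d_int <- vapply(int_genes, pair_dist, 1)
  expect_gte(mean(d_f2 < quantile(d_int, 0.1)), 0.95)

  # unbalanced design errors with the offending combination
  meta_bad <- sim$bundle$metadata
  meta_bad$batch[meta_bad$sample_id == "sample01"] <- "b"
  expect_error(pca_multifactor(v, meta_bad, "condition", "batch", ntop = 50),
               "unbalanced")
})
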