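# GO over-representation of high-loading genes.

make_go <- function(terms) go_annotation(terms)

test_that("select_loading_quantile applies the ceiling and sign rules", {
  set.seed(6)
  ld <- matrix(rnorm(100), ncol = 1, dimnames = list(sprintf("g%03d", 1:100), "PC1"))
  p <- structure(list(loadings = ld, variable_ids = rownames(ld)),
                 class = "pca_result")
  sel <- select_loading_quantile(p, 1, "positive", 0.025)
  expect_equal(nrow(sel), 3)  # ceil(0.025 * 100)
  expect_true(all(sel$loading > 0))
  expect_equal(sel$loading, sort(ld[ld[, 1] > 0, 1], decreasing = TRUE)[1:3],
               ignore_attr = TRUE)

  neg <- structure(list(
    loadings = matrix(-abs(rnorm(10)), ncol = 1,
                      dimnames = list(paste0("g", 1:10), "PC1")),
    variable_ids = paste0("g", 1:10)
  ), class = "pca_result")
  expect_warning(sel0 <- select_loading_quantile(neg, 1, "positive"),
                 "no genes")
  expect_equal(nrow(sel0), 0)

  four <- structure(list(
    loadings = matrix(c(0.9, 0.5, -0.5, -0.9), ncol = 1,
                      dimnames = list(paste0("g", 1:4), "PC1")),
    variable_ids = paste0("g", 1:4)
  ), class = "pca_result")
  sel2 <- select_loading_quantile(four, 1, "positive", 0.5)
  expect_equal(sel2$gene_id, c("g1", "g2"))
})

test_that("enrich_fisher matches hand-computed hypergeometric tails", {
  uni <- paste0("g", 1:10)
  # a background term annotating every universe gene keeps N = 10 (the
  # annotated universe is the union of the term gene sets)
  go <- make_go(list("GO:0000001" = paste0("g", 1:4), "GO:0000099" = uni))
  # k = 3 of K = 4 in a draw of n = 3: p = C(4,3)/C(10,3) = 1/30
  tab <- enrich_fisher(paste0("g", 1:3), uni, go, min_term_size = 1,
                       max_term_size = 10)
  row <- tab[tab$term_id == "GO:0000001", ]
  expect_equal(row$p_value, 4 / 120, tolerance = 1e-12)
  expect_equal(row$n_annotated_selected, 3)
  expect_equal(row$expected, 3 * 4 / 10)

  # k = 0: the whole support, p = 1
  tab0 <- enrich_fisher(paste0("g", 8:10), uni, go, min_term_size = 1,
                        max_term_size = 10)
  expect_equal(tab0$p_value[tab0$term_id == "GO:0000001"], 1)

  # term covering the whole universe: k = n, p = 1
  go_all <- make_go(list("GO:0000002" = uni))
  tab_all <- enrich_fisher(paste0("g", 1:3), uni, go_all, min_term_size = 1,
                           max_term_size = 10)
  expect_equal(tab_all$p_value, 1)

  expect_error(enrich_fisher("gX", uni, go), "subset")
  expect_equal(nrow(enrich_fisher(character(0), uni, go)), 0)
})

test_that("enrich_fisher equals exhaustive enumeration on small universes", {
  for (N in c(6, 9, 12)) {
    uni <- paste0("g", seq_len(N))
    for (K in c(2, floor(N / 2), N - 1)) {
      go <- make_go(list("GO:0000001" = paste0("g", seq_len(K)),
                         "GO:0000099" = uni))
      for (n in c(2, floor(N / 2), N - 1)) {
        for (k in unique(c(0, 1, min(K, n)))) {
          if (k > K || n - k > N - K) next
          selected <- c(paste0("g", seq_len(K))[seq_len(k)],
                        rev(paste0("g", seq_len(N)))[seq_len(n - k)])
          tab <- enrich_fisher(selected, uni, go, min_term_size = 1,
                               max_term_size = N)
          expect_equal(tab$p_value[tab$term_id == "GO:0000001"],
                       enum_tail_oracle(N, K, n, k), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("BH FDR is monotone over the p-ordered table", {
  set.seed(12)
  genes <- sprintf("g%03d", 1:60)
  terms <- setNames(
    lapply(1:12, function(i) sample(genes, sample(5:20, 1))),
    sprintf("GO:%07d", 1:12)
  )
  tab <- enrich_fisher(sample(genes, 15), genes, make_go(terms),
                       min_term_size = 1, max_term_size = 60)
  expect_true(all(diff(tab$fdr) >= -1e-12))
  expect_true(all(tab$fdr >= tab$p_value - 1e-12))
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
  expect_true(all(tab$n_annotated_selected <=
                    pmin(tab$n_annotated_universe, 15)))
})

test_that("pca2go_all annotates each component and direction", {
  world <- default_world()
  tg <- world$sim$truth$genes
  pca <- pca_samples(world$vst, ntop = 500)
  up_genes <- tg$gene_id[tg$affected & tg$lfc > 0]
  go <- simulate_go(tg$gene_id, up_genes, seed = 42)

  enr <- pca2go_all(pca, go, pcs = 1:2)
  expect_s3_class(enr, "pc_enrichment")
  expect_setequal(
    unique(paste(enr$pc, enr$direction)),
    c("1 positive", "1 negative", "2 positive", "2 negative")
  )
  sels <- attr(enr, "selections")
  expect_length(sels, 4)
  expect_equal(nrow(sels$PC1_positive), ceiling(0.025 * 500))

  # the planted term tops the matching direction of PC1
  up_in <- intersect(up_genes, pca$variable_ids)
  dir_match <- if (mean(pca$loadings[up_in, 1]) > 0) "positive" else "negative"
  top_row <- dplyr::filter(enr, pc == 1, direction == dir_match) |>
    dplyr::slice_min(p_value, n = 1)
  expect_equal(top_row$term_id, attr(go, "planted_term"))
  expect_lt(top_row$p_value, 1e-4)

  expect_error(pca2go_all(pca, go, pcs = 1:50), "retained")
  go_foreign <- go_annotation(list("GO:0000009" = c("zz1", "zz2")))
  expect_error(pca2go_all(pca, go_foreign), "no genes")
})

test_that("permuting the annotation destroys the planted signal", {
  world <- default_world()
  tg <- world$sim$truth$genes
  pca <- pca_samples(world$vst, ntop = 500)
  up_genes <- tg$gene_id[tg$affected & tg$lfc > 0]
  go <- simulate_go(tg$gene_id, up_genes, seed = 42)
  planted <- attr(go, "planted_term")
  up_in <- intersect(up_genes, pca$variable_ids)
  dir_match <- if (mean(pca$loadings[up_in, 1]) > 0) "positive" else "negative"
  sel <- select_loading_quantile(pca, 1, dir_match)
  universe <- intersect(pca$variable_ids,
                        unique(unlist(go$term_to_genes, use.names = FALSE)))

  set.seed(99)
  n_perm <- 50
  null_p <- vapply(seq_len(n_perm), function(i) {
    relabel <- setNames(sample(tg$gene_id), tg$gene_id)
    go_perm <- go_annotation(
      lapply(go$term_to_genes, function(g) sort(unname(relabel[g]))))
    uni_perm <- intersect(pca$variable_ids,
                          unique(unlist(go_perm$term_to_genes, use.names = FALSE)))
    tab <- enrich_fisher(intersect(sel$gene_id, uni_perm), uni_perm, go_perm)
    p <- tab$p_value[tab$term_id == planted]
    if (length(p) == 0) 1 else p
  }, 1)
  expect_gte(mean(null_p > 0.05), 0.9)
})
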