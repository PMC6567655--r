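# Shared fixture builders; everything is generated in code at test time.

toy_counts <- function() {
  matrix(c(2, 4, 6, 4, 8, 12), nrow = 3,
         dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# A small labelled matrix of transformed-scale values.
toy_transformed <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  as_transformed(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The stated simulation world used across the suite (defaults of
# simulation_design, fixture seed 42), fully processed.  Cached per session
# because several test files reuse it.
default_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_counts(simulation_design(seed = 42))
      sf <- estimate_size_factors(sim$bundle$counts)
      trend <- fit_dispersion_trend(sim$bundle$counts, sf)
      cache <<- list(
        sim = sim, sf = sf, trend = trend,
        vst = vst(sim$bundle$counts, sf, trend)
      )
    }
    cache
  }
})

# Write a simulated experiment to disk as pipeline inputs.
write_world_inputs <- function(sim, dir = tempfile("world")) {
  dir.create(dir)
  write_table(sim$bundle$counts, file.path(dir, "counts.tsv"))
  write_table(as.data.frame(sim$bundle$metadata), file.path(dir, "metadata.tsv"))
  go <- simulate_go(
    sim$truth$genes$gene_id,
    sim$truth$genes$gene_id[sim$truth$genes$affected & sim$truth$genes$lfc > 0],
    seed = 42
  )
  pairs <- data.frame(
    gene_id = unlist(go$term_to_genes, use.names = FALSE),
    go_id = rep(names(go$term_to_genes), lengths(go$term_to_genes))
  )
  write.table(pairs, file.path(dir, "go.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  list(dir = dir, counts = file.path(dir, "counts.tsv"),
       metadata = file.path(dir, "metadata.tsv"),
       go = file.path(dir, "go.tsv"), go_obj = go)
}

# Independent PCA oracle: eigendecomposition of the sample covariance of
# the centered observations-x-variables matrix.
eigen_pca_oracle <- function(X) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  C <- crossprod(Xc) / (nrow(X) - 1)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  list(variance_explained = ev / sum(ev),
       scores = Xc %*% e$vectors,
       eigenvalues = ev)
}

# Independent hypergeometric oracle: exhaustive enumeration of all
# C(N, n) draws; term = elements 1..K of the universe 1..N.
enum_tail_oracle <- function(N, K, n, k0) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k0)
}
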