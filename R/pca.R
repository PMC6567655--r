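#' Rank genes by variance of transformed values
#'
#' Genes are ranked by the row variance of the transformed matrix,
#' descending; ties are broken by input row order (stable).  If `ntop`
#' exceeds the number of genes, all genes are returned.
#'
#' @param transformed A `transformed_matrix` (or plain labelled matrix).
#' @param ntop Number of most-variable genes to keep (default 500).
#' @return Character vector of gene IDs, most variable first.
#' @export
select_top_variable <- function(transformed, ntop = 500) {
  x <- tm_values(transformed)
  if (!is.numeric(ntop) || length(ntop) != 1 || ntop < 2) {
    stop("`ntop` must be a single integer >= 2", call. = FALSE)
  }
  rv <- row_vars(x)
  if (all(rv == 0)) {
    warning("all gene variances are zero; returning genes in input order",
            call. = FALSE)
  }
  ord <- order(-rv, seq_along(rv))
  rownames(x)[ord[seq_len(min(ntop, nrow(x)))]]
}

# Shared PCA core: rows of `mat` are observations, columns are variables.
# Columns are assumed already centered/scaled by the caller; applies the
# deterministic sign convention (largest-|loading| entry positive).
pca_core <- function(mat, observation_ids, variable_ids) {
  p <- prcomp(mat, center = FALSE, scale. = FALSE)
  k <- length(p$sdev)
  scores <- p$x[, seq_len(k), drop = FALSE]
  loadings <- p$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- p$sdev[seq_len(k)]^2
  ve <- ev / sum(ev)
  rownames(scores) <- observation_ids
  rownames(loadings) <- variable_ids
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  list(scores = scores, loadings = loadings, sdev = p$sdev[seq_len(k)],
       variance_explained = as.numeric(ve))
}

new_pca_result <- function(core, kind, ntop, centered = TRUE, scaled = FALSE,
                           arrows = NULL) {
  structure(
    list(scores = core$scores, loadings = core$loadings,
         variance_explained = core$variance_explained, sdev = core$sdev,
         observation_ids = rownames(core$scores),
         variable_ids = rownames(core$loadings),
         ntop = ntop, centered = centered, scaled = scaled,
         kind = kind, arrows = arrows),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> kind: %s; %d observations x %d variables (ntop = %d)\n",
              x$kind, length(x$observation_ids), length(x$variable_ids), x$ntop))
  ve <- head(x$variance_explained, 5)
  cat("  variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_along(ve), 100 * ve), collapse = ", "),
      if (length(x$variance_explained) > 5) "..." else "", "\n")
  invisible(x)
}

#' PCA of samples over the most-variable genes
#'
#' Observations are samples; variables are the `ntop` most-variable genes
#' (chosen with [select_top_variable()]).  Gene columns are mean-centered;
#' when `scale = TRUE` they are additionally divided by their standard
#' deviation (zero-variance genes are dropped with a warning).  Loading
#' columns follow a deterministic sign convention: the entry of largest
#' absolute value is positive.
#'
#' @inheritParams select_top_variable
#' @param scale Divide each gene by its standard deviation (default `FALSE`;
#'   variance-stabilized data are already on a common scale).
#' @return A `pca_result` with sample scores, gene loadings and the
#'   variance explained per component.
#' @export
pca_samples <- function(transformed, ntop = 500, scale = FALSE) {
  x <- tm_values(transformed)
  if (ncol(x) < 2) stop("at least 2 samples are required for PCA", call. = FALSE)
  top <- select_top_variable(transformed, ntop)
  X <- t(x[top, , drop = FALSE])          # samples x genes
  X <- scale(X, center = TRUE, scale = FALSE)
  if (scale) {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0)) {
      warning(sum(sds == 0), " zero-variance gene(s) dropped before scaling",
              call. = FALSE)
      X <- X[, sds > 0, drop = FALSE]
      sds <- sds[sds > 0]
    }
    X <- sweep(X, 2, sds, "/")
  }
  core <- pca_core(X, rownames(X), colnames(X))
  new_pca_result(core, "samples", ntop = length(top), scaled = scale)
}

#' Scree table
#'
#' Variance explained per component with its running sum, used to choose
#' how many components to inspect.
#'
#' @param pca A `pca_result`.
#' @return A tibble with columns `component`, `variance_explained`,
#'   `cumulative`.
#' @export
scree <- function(pca) {
  stopifnot(inherits(pca, "pca_result"))
  ve <- pca$variance_explained
  tibble::tibble(
    component = seq_along(ve),
    variance_explained = ve,
    cumulative = cumsum(ve)
  )
}

new_gene_subset <- function(gene_ids, loadings, pc, direction) {
  out <- tibble::tibble(gene_id = gene_ids, loading = loadings)
  attr(out, "pc") <- pc
  attr(out, "direction") <- direction
  class(out) <- c("gene_subset", class(out))
  out
}

#' Genes with the highest loadings on a component
#'
#' Returns the `n_per_direction` genes with the most positive loadings and
#' the `n_per_direction` with the most negative loadings on the chosen PC,
#' each ordered by absolute loading, descending.  Fewer genes are returned
#' when not enough genes of the requested sign exist.
#'
#' @param pca A `pca_result`.
#' @param pc Component index (1-based).
#' @param n_per_direction Number of genes per direction (default 10).
#' @return A list with elements `positive` and `negative`, each a
#'   `gene_subset` tibble (`gene_id`, `loading`).
#' @export
hi_loadings <- function(pca, pc, n_per_direction = 10) {
  stopifnot(inherits(pca, "pca_result"))
  if (!is.numeric(pc) || length(pc) != 1 || pc < 1 ||
      pc > ncol(pca$loadings)) {
    stop(sprintf("`pc` must be in 1..%d", ncol(pca$loadings)), call. = FALSE)
  }
  ld <- pca$loadings[, pc]
  pick <- function(direction) {
    keep <- if (direction == "positive") which(ld > 0) else which(ld < 0)
    keep <- keep[order(-abs(ld[keep]), keep)]
    keep <- head(keep, n_per_direction)
    new_gene_subset(pca$variable_ids[keep], unname(ld[keep]), pc, direction)
  }
  list(positive = pick("positive"), negative = pick("negative"))
}

#' Recompute the sample PCA after removing samples
#'
#' Used to explore the effect of dropping outlier samples.  Both the
#' variable-gene ranking and the PCA are recomputed on the reduced sample
#' set (this is not a projection of the original PCA).
#'
#' @inheritParams pca_samples
#' @param drop Character vector of sample IDs to remove.
#' @return A `pca_result` on the remaining samples.
#' @export
pca_remove_samples <- function(transformed, drop, ntop = 500, scale = FALSE) {
  x <- tm_values(transformed)
  unknown <- setdiff(drop, colnames(x))
  if (length(unknown)) {
    stop("unknown sample ID(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- setdiff(colnames(x), drop)
  if (length(keep) < 2) {
    stop("fewer than 2 samples would remain after removal", call. = FALSE)
  }
  pca_samples(tm_subset_samples(transformed, keep), ntop = ntop, scale = scale)
}

#' PCA of genes with biplot coordinates
#'
#' Observations are the `ntop` most-variable genes, each row centered
#' across samples; variables are the samples.  The result additionally
#' carries biplot sample arrows: the sample loadings scaled by the square
#' root of each component's eigenvalue (correlation-biplot convention).
#'
#' @inheritParams pca_samples
#' @return A `pca_result` of kind `"genes"` whose `arrows` element is a
#'   samples x components matrix of biplot arrow coordinates.
#' @export
pca_genes <- function(transformed, ntop = 500) {
  x <- tm_values(transformed)
  if (ncol(x) < 2) stop("at least 2 samples are required for PCA", call. = FALSE)
  top <- select_top_variable(transformed, ntop)
  X <- x[top, , drop = FALSE]
  X <- X - rowMeans(X)                      # genes x samples, rows centered
  core <- pca_core(X, rownames(X), colnames(X))
  arrows <- sweep(core$loadings, 2, core$sdev, "*")
  new_pca_result(core, "genes", ntop = length(top), arrows = arrows)
}

#' Select genes inside a score rectangle
#'
#' Programmatic equivalent of brushing a region of the gene PCA plot:
#' returns the genes whose scores on the two chosen components fall inside
#' the closed rectangle, ordered by their score along the first component.
#'
#' @param pca A `pca_result` from [pca_genes()].
#' @param pc_x,pc_y Component indices for the two axes.
#' @param x_range,y_range Numeric length-2 intervals (closed on all
#'   boundaries).
#' @return Character vector of gene IDs (possibly empty).
#' @export
select_genes_in_box <- function(pca, pc_x, pc_y, x_range, y_range) {
  stopifnot(inherits(pca, "pca_result"))
  k <- ncol(pca$scores)
  if (pc_x < 1 || pc_x > k || pc_y < 1 || pc_y > k) {
    stop(sprintf("components must be in 1..%d", k), call. = FALSE)
  }
  sx <- pca$scores[, pc_x]
  sy <- pca$scores[, pc_y]
  x_range <- sort(as.numeric(x_range))
  y_range <- sort(as.numeric(y_range))
  inside <- sx >= x_range[1] & sx <= x_range[2] &
    sy >= y_range[1] & sy <= y_range[2]
  ids <- pca$observation_ids[inside]
  ids[order(sx[inside])]
}

#' Per-gene expression profiles across samples
#'
#' Transformed values for a gene subset, one row per gene, columns in the
#' sample order of the matrix; with `center = TRUE` (default) each row has
#' its mean subtracted, which is the usual display for profile plots.
#'
#' @inheritParams select_top_variable
#' @param gene_ids Character vector of gene IDs (must all exist).
#' @param center Subtract each gene's mean (default `TRUE`).
#' @return A tibble with a `gene_id` column followed by one column per
#'   sample.
#' @export
profile_data <- function(transformed, gene_ids, center = TRUE) {
  x <- tm_values(transformed)
  unknown <- setdiff(gene_ids, rownames(x))
  if (length(unknown)) {
    stop("unknown gene ID(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  m <- x[gene_ids, , drop = FALSE]
  if (center) m <- m - rowMeans(m)
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  dplyr::bind_cols(tibble::tibble(gene_id = gene_ids), out)
}

#' Two-factor stacked PCA
#'
#' Incorporates two experimental factors into one PCA: the observation
#' matrix has one row per (gene, factor1 level) pair — identified as
#' `"gene::level"` — and one column per (factor2 level, replicate) pair.
#' Each entry is the transformed value of the corresponding sample.  The
#' design must be balanced: every factor1 x factor2 combination must hold
#' the same number of samples.  Rows are centered before the PCA, so genes
#' whose rows (one per factor1 level) land close together respond to
#' factor2 alone, while separated rows indicate a factor1 effect or an
#' interaction.
#'
#' @inheritParams pca_samples
#' @param metadata Sample metadata tibble with a `sample_id` column.
#' @param factor1,factor2 Names of the two factor columns in `metadata`.
#' @return A `pca_result` of kind `"multifactor"` whose observation IDs are
#'   `"gene::level"` pairs.
#' @export
pca_multifactor <- function(transformed, metadata, factor1, factor2, ntop = 500) {
  x <- tm_values(transformed)
  stopifnot(is.data.frame(metadata), "sample_id" %in% names(metadata))
  for (f in c(factor1, factor2)) {
    if (!f %in% names(metadata)) stop("unknown factor: ", f, call. = FALSE)
  }
  meta <- metadata[match(colnames(x), metadata$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) {
    stop("metadata does not cover all samples of the matrix", call. = FALSE)
  }
  f1 <- as.character(meta[[factor1]])
  f2 <- as.character(meta[[factor2]])
  l1 <- sort(unique(f1))
  l2 <- sort(unique(f2))
  tab <- table(factor(f1, l1), factor(f2, l2))
  if (length(unique(as.vector(tab))) != 1 || any(tab == 0)) {
    bad <- paste(sprintf("%s x %s: %d", rep(l1, ncol(tab)),
                         rep(l2, each = nrow(tab)), as.vector(t(tab))),
                 collapse = "; ")
    stop("unbalanced design for ", factor1, " x ", factor2, " (", bad, ")",
         call. = FALSE)
  }
  reps <- as.vector(tab)[1]
  top <- select_top_variable(transformed, ntop)
  # Column layout: factor2 levels, replicates within each level in
  # metadata sample order.
  col_sample <- matrix("", nrow = length(l1), ncol = length(l2) * reps)
  for (i in seq_along(l1)) {
    cols <- character(0)
    for (j in seq_along(l2)) {
      cols <- c(cols, colnames(x)[f1 == l1[i] & f2 == l2[j]])
    }
    col_sample[i, ] <- cols
  }
  col_ids <- paste(rep(l2, each = reps), rep(seq_len(reps), length(l2)),
                   sep = "::")
  stacked <- do.call(rbind, lapply(seq_along(l1), function(i) {
    m <- x[top, col_sample[i, ], drop = FALSE]
    rownames(m) <- paste(top, l1[i], sep = "::")
    colnames(m) <- col_ids
    m
  }))
  # Interleave so all rows of a gene are adjacent: gene1::A, gene1::B, ...
  ord <- as.vector(t(matrix(seq_len(nrow(stacked)), ncol = length(l1))))
  stacked <- stacked[ord, , drop = FALSE]
  stacked <- stacked - rowMeans(stacked)
  core <- pca_core(stacked, rownames(stacked), colnames(stacked))
  res <- new_pca_result(core, "multifactor", ntop = length(top))
  res$factors <- c(factor1, factor2)
  res
}
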