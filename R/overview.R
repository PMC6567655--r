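#' Library sizes
#'
#' Per-sample total read counts, also expressed in millions.
#'
#' @inheritParams estimate_size_factors
#' @return A tibble with columns `sample_id`, `total_counts`, `millions`.
#' @export
library_sizes <- function(counts) {
  check_counts(counts)
  totals <- colSums(counts)
  if (any(totals == 0)) {
    log_info("library_sizes: sample(s) with zero total counts: %s",
             paste(colnames(counts)[totals == 0], collapse = ", "))
  }
  tibble::tibble(
    sample_id = colnames(counts),
    total_counts = unname(totals),
    millions = unname(totals) / 1e6
  )
}

#' Robustly detected genes
#'
#' A gene counts as detected in a sample when its count reaches
#' `min_count`; it is robustly detected overall when that happens in at
#' least `min_samples` samples.
#'
#' @inheritParams estimate_size_factors
#' @param min_count Minimum count for a gene to be called detected in a
#'   sample (default 5).
#' @param min_samples Minimum number of samples for the robust total
#'   (default 1).
#' @return A list of class `detected_genes` with `per_sample` (tibble of
#'   per-sample detected gene numbers) and `robust_total` (scalar).
#' @export
detected_genes <- function(counts, min_count = 5, min_samples = 1) {
  check_counts(counts)
  stopifnot(min_count >= 1, min_samples >= 1)
  hits <- counts >= min_count
  per_sample <- tibble::tibble(
    sample_id = colnames(counts),
    detected = unname(colSums(hits))
  )
  robust_total <- sum(rowSums(hits) >= min_samples)
  structure(
    list(per_sample = per_sample, robust_total = robust_total,
         min_count = min_count, min_samples = min_samples),
    class = "detected_genes"
  )
}

#' @export
print.detected_genes <- function(x, ...) {
  cat(sprintf("<detected_genes> %d genes with count >= %d in >= %d sample(s)\n",
              x$robust_total, x$min_count, x$min_samples))
  print(x$per_sample)
  invisible(x)
}

#' Euclidean distances between samples
#'
#' Pairwise Euclidean distances between samples over all genes of the
#' transformed matrix, with a sample ordering from average-linkage
#' hierarchical clustering for heatmap display.
#'
#' @inheritParams select_top_variable
#' @return A list of class `sample_dist` with `values` (symmetric matrix),
#'   `metric`, `dendrogram_order` (sample IDs in clustering order) and the
#'   `hclust` object.
#' @export
sample_distances <- function(transformed) {
  x <- tm_values(transformed)
  if (ncol(x) < 2) stop("at least 2 samples are required", call. = FALSE)
  d <- dist(t(x), method = "euclidean")
  hc <- hclust(d, method = "average")
  m <- as.matrix(d)
  structure(
    list(values = m, metric = "euclidean",
         dendrogram_order = colnames(x)[hc$order], hclust = hc),
    class = "sample_dist"
  )
}

#' @export
print.sample_dist <- function(x, ...) {
  cat(sprintf("<sample_dist> %d samples, metric: %s\n  dendrogram order: %s\n",
              nrow(x$values), x$metric,
              paste(x$dendrogram_order, collapse = ", ")))
  invisible(x)
}

#' Sample-sample correlation matrix
#'
#' Pairwise correlation of the per-sample normalized count vectors.
#' Zero-variance samples yield missing rows/columns with a warning.
#'
#' @param normalized Numeric matrix of normalized counts (genes x samples),
#'   e.g. from [normalize_counts()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(normalized, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.matrix(normalized), is.numeric(normalized))
  if (ncol(normalized) < 2) stop("at least 2 samples are required", call. = FALSE)
  sds <- apply(normalized, 2, stats::sd)
  bad <- sds == 0
  if (any(bad)) {
    warning("zero-variance sample(s) set to NA: ",
            paste(colnames(normalized)[bad], collapse = ", "), call. = FALSE)
  }
  cc <- suppressWarnings(cor(normalized, method = method))
  cc[bad, ] <- NA_real_
  cc[, bad] <- NA_real_
  diag(cc)[!bad] <- 1
  cc
}

#' Summarise one gene across sample groups
#'
#' Looks a gene up by primary ID or by any alternative ID in the bundle's
#' annotation (exact match; a unique hit is required), partitions the
#' samples by the cross-product of the named experimental factors, and
#' summarises the transformed values per group (n, min, quartiles by the
#' linear-interpolation convention, max) alongside the individual points.
#'
#' @param bundle An `experiment_bundle`.
#' @param transformed A `transformed_matrix` on the bundle's samples.
#' @param query Gene ID or alternative ID/symbol.
#' @param group_by Character vector of factor column names in the metadata.
#' @return A list of class `gene_summary` with `gene_id`, `query`,
#'   `summary` (one row per group) and `points` (one row per sample).
#' @export
gene_finder <- function(bundle, transformed, query, group_by) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  x <- tm_values(transformed)
  gene_id <- resolve_gene(bundle, query)
  if (!gene_id %in% rownames(x)) {
    stop("gene '", gene_id, "' not present in the transformed matrix", call. = FALSE)
  }
  meta <- bundle$metadata[match(colnames(x), bundle$metadata$sample_id), ,
                          drop = FALSE]
  missing_f <- setdiff(group_by, names(meta))
  if (length(missing_f)) {
    stop("unknown factor(s): ", paste(missing_f, collapse = ", "), call. = FALSE)
  }
  labels <- do.call(paste, c(lapply(group_by, function(f) as.character(meta[[f]])),
                             sep = ":"))
  points <- tibble::tibble(
    sample_id = colnames(x),
    group = labels,
    value = unname(x[gene_id, ])
  )
  summary <- points |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      min = min(.data$value),
      q1 = quantile(.data$value, 0.25, type = 7, names = FALSE),
      median = median(.data$value),
      q3 = quantile(.data$value, 0.75, type = 7, names = FALSE),
      max = max(.data$value),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$group)
  structure(
    list(gene_id = gene_id, query = query, group_by = group_by,
         summary = summary, points = points),
    class = "gene_summary"
  )
}

#' @export
print.gene_summary <- function(x, ...) {
  cat(sprintf("<gene_summary> %s grouped by %s\n", x$gene_id,
              paste(x$group_by, collapse = " x ")))
  print(x$summary)
  invisible(x)
}

# Resolve a query against primary gene IDs, then annotation alternative IDs.
resolve_gene <- function(bundle, query) {
  ids <- rownames(bundle$counts)
  if (query %in% ids) return(query)
  if (!is.null(bundle$annotation)) {
    ann <- bundle$annotation
    hits <- character(0)
    for (col in setdiff(names(ann), "gene_id")) {
      hits <- c(hits, ann$gene_id[!is.na(ann[[col]]) & ann[[col]] == query])
    }
    hits <- unique(hits[hits %in% ids])
    if (length(hits) == 1) return(hits)
    if (length(hits) > 1) {
      stop("ambiguous query '", query, "': matches ",
           paste(hits, collapse = ", "), call. = FALSE)
    }
  }
  near <- ids[startsWith(ids, query)]
  if (!is.null(bundle$annotation)) {
    for (col in setdiff(names(bundle$annotation), "gene_id")) {
      v <- bundle$annotation[[col]]
      near <- c(near, bundle$annotation$gene_id[!is.na(v) & startsWith(v, query)])
    }
  }
  near <- unique(near)
  stop("no gene matches '", query, "'",
       if (length(near)) paste0("; did you mean: ",
                                paste(head(near, 5), collapse = ", "), "?") else "",
       call. = FALSE)
}
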