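#' Select the top loading quantile of a component, per direction
#'
#' The `ceil(top_fraction * n_variables)` genes with the most extreme
#' loadings in the requested direction; genes whose loading has the wrong
#' sign are excluded even when within the count, so the selection can be
#' smaller (or empty, with a warning).
#'
#' @param pca A `pca_result`.
#' @param pc Component index (1-based).
#' @param direction `"positive"` or `"negative"`.
#' @param top_fraction Fraction of variables to select, in (0, 0.5]
#'   (default 0.025, i.e. 2.5 percent per direction).
#' @return A `gene_subset` tibble (`gene_id`, `loading`) ordered by
#'   absolute loading, descending.
#' @export
select_loading_quantile <- function(pca, pc, direction = c("positive", "negative"),
                                    top_fraction = 0.025) {
  stopifnot(inherits(pca, "pca_result"))
  direction <- match.arg(direction)
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction > 0.5) {
    stop("`top_fraction` must be in (0, 0.5]", call. = FALSE)
  }
  if (pc < 1 || pc > ncol(pca$loadings)) {
    stop(sprintf("`pc` must be in 1..%d", ncol(pca$loadings)), call. = FALSE)
  }
  ld <- pca$loadings[, pc]
  n_sel <- ceiling(top_fraction * length(ld))
  keep <- if (direction == "positive") which(ld > 0) else which(ld < 0)
  keep <- keep[order(-abs(ld[keep]), keep)]
  keep <- head(keep, n_sel)
  if (length(keep) == 0) {
    warning(sprintf("no genes with %s loading on PC%d", direction, pc),
            call. = FALSE)
  }
  new_gene_subset(pca$variable_ids[keep], unname(ld[keep]), pc, direction)
}

#' Hypergeometric over-representation test
#'
#' For every GO term whose annotated-in-universe size lies in
#' `[min_term_size, max_term_size]`, tests whether the selected gene set
#' contains more of the term's genes than expected under random sampling:
#' the one-sided upper-tail hypergeometric probability `P(X >= k)` with
#' `k = |term & selected|`, `K = |term & universe|`,
#' `n = |selected & annotated universe|` and `N = |annotated universe|`
#' (the universe restricted to genes with at least one annotation).
#' P-values are adjusted across the tested terms by Benjamini-Hochberg.
#'
#' @param selected Character vector of selected gene IDs (must be a subset
#'   of `universe`).
#' @param universe Character vector of background gene IDs.
#' @param go A `go_annotation`.
#' @param min_term_size,max_term_size Bounds on the in-universe term size
#'   for a term to be tested (defaults 5 and 500).
#' @return A tibble with columns `term_id`, `term_name`,
#'   `n_annotated_universe`, `n_annotated_selected`, `expected`, `p_value`,
#'   `fdr`, sorted by p-value (ties by term ID).
#' @export
enrich_fisher <- function(selected, universe, go,
                          min_term_size = 5, max_term_size = 500) {
  stopifnot(inherits(go, "go_annotation"))
  selected <- unique(as.character(selected))
  universe <- unique(as.character(universe))
  if (!all(selected %in% universe)) {
    stop("`selected` must be a subset of `universe`", call. = FALSE)
  }
  empty <- tibble::tibble(
    term_id = character(0), term_name = character(0),
    n_annotated_universe = integer(0), n_annotated_selected = integer(0),
    expected = numeric(0), p_value = numeric(0), fdr = numeric(0)
  )
  if (length(selected) == 0) return(empty)
  annotated <- unique(unlist(go$term_to_genes, use.names = FALSE))
  ann_universe <- intersect(universe, annotated)
  if (length(ann_universe) == 0) {
    stop("the universe shares no genes with the GO annotation", call. = FALSE)
  }
  N <- length(ann_universe)
  n <- length(intersect(selected, ann_universe))
  K <- vapply(go$term_to_genes,
              function(g) length(intersect(g, ann_universe)), 1L)
  test <- K >= min_term_size & K <= max_term_size
  if (!any(test)) return(empty)
  term_ids <- names(go$term_to_genes)[test]
  K <- K[test]
  k <- vapply(go$term_to_genes[test],
              function(g) length(intersect(g, selected)), 1L)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- tibble::tibble(
    term_id = term_ids,
    term_name = unname(go$term_names[term_ids]),
    n_annotated_universe = unname(K),
    n_annotated_selected = unname(k),
    expected = unname(n * K / N),
    p_value = unname(p),
    fdr = p.adjust(unname(p), method = "BH")
  )
  dplyr::arrange(out, .data$p_value, .data$term_id)
}

#' Functional annotation of principal components
#'
#' For every requested component and each direction, selects the genes with
#' the most extreme loadings ([select_loading_quantile()]) and tests GO
#' terms for over-representation among them ([enrich_fisher()]).  By
#' default the universe is the PCA's own variables (the `ntop`
#' most-variable genes) intersected with the annotated genes, so the
#' enrichment is conditional on the genes actually driving the components;
#' set `universe = "annotated"` to use all annotated genes instead.
#'
#' @param pca A `pca_result` (typically from [pca_samples()]).
#' @param go A `go_annotation`.
#' @param pcs Integer vector of components to annotate (default `1:4`; all
#'   must be retained in `pca`).
#' @inheritParams select_loading_quantile
#' @inheritParams enrich_fisher
#' @param universe `"ntop"` (default) or `"annotated"`.
#' @return A tibble of class `pc_enrichment` in long format with columns
#'   `pc`, `direction` and the [enrich_fisher()] columns, ordered by
#'   (pc, direction, p-value).  The per-(pc, direction) gene selections and
#'   the test parameters are attached as attributes `selections` and
#'   `params`.
#' @export
pca2go_all <- function(pca, go, pcs = 1:4, top_fraction = 0.025,
                       min_term_size = 5, max_term_size = 500,
                       universe = c("ntop", "annotated")) {
  stopifnot(inherits(pca, "pca_result"), inherits(go, "go_annotation"))
  universe <- match.arg(universe)
  k <- ncol(pca$loadings)
  if (any(pcs < 1) || any(pcs > k)) {
    stop(sprintf("`pcs` must lie within the retained components (1..%d)", k),
         call. = FALSE)
  }
  annotated <- unique(unlist(go$term_to_genes, use.names = FALSE))
  uni <- if (universe == "ntop") {
    intersect(pca$variable_ids, annotated)
  } else {
    annotated
  }
  if (length(uni) == 0) {
    stop("the GO annotation shares no genes with the PCA variables", call. = FALSE)
  }
  selections <- list()
  rows <- list()
  for (pc in pcs) {
    for (direction in c("positive", "negative")) {
      sel <- select_loading_quantile(pca, pc, direction, top_fraction)
      key <- sprintf("PC%d_%s", pc, direction)
      selections[[key]] <- sel
      tab <- enrich_fisher(intersect(sel$gene_id, uni), uni, go,
                           min_term_size, max_term_size)
      if (nrow(tab)) {
        rows[[key]] <- dplyr::bind_cols(
          tibble::tibble(pc = pc, direction = direction), tab)
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    pc = integer(0), direction = character(0), term_id = character(0),
    term_name = character(0), n_annotated_universe = integer(0),
    n_annotated_selected = integer(0), expected = numeric(0),
    p_value = numeric(0), fdr = numeric(0)
  )
  out <- dplyr::arrange(out, .data$pc,
                        factor(.data$direction, c("positive", "negative")),
                        .data$p_value, .data$term_id)
  attr(out, "selections") <- selections
  attr(out, "params") <- list(
    pcs = pcs, top_fraction = top_fraction, min_term_size = min_term_size,
    max_term_size = max_term_size, universe = universe,
    universe_size = length(uni)
  )
  class(out) <- c("pc_enrichment", class(out))
  out
}

#' Write an enrichment set as TSV with a parameter header
#'
#' Writes the combined long-format enrichment table with the test
#' parameters echoed in `#`-prefixed header comment lines.
#'
#' @param x A `pc_enrichment` from [pca2go_all()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_enrichment <- function(x, path) {
  stopifnot(inherits(x, "pc_enrichment"))
  params <- attr(x, "params")
  hdr <- vapply(names(params), function(nm) {
    sprintf("# %s: %s", nm, paste(params[[nm]], collapse = ","))
  }, "")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_table(as.data.frame(x), tmp)
  writeLines(c(hdr, readLines(tmp, warn = FALSE)), path)
  invisible(path)
}
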