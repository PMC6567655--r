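# Templated, self-contained HTML report from a session state.

#' Describe a report
#'
#' @param sections Sections to include, a subset of `"overview"`,
#'   `"samples_pca"`, `"genes_pca"`, `"pca2go"`, `"multifactor"`.
#' @param figure_format `"svg"` (inline vector figures, default) or
#'   `"none"` (tables only).
#' @param title Report title.
#' @return A `report_spec` list.
#' @export
report_spec <- function(sections = c("overview", "samples_pca", "genes_pca"),
                        figure_format = c("svg", "none"),
                        title = "Exploratory PCA report") {
  known <- c("overview", "samples_pca", "genes_pca", "pca2go", "multifactor")
  bad <- setdiff(sections, known)
  if (length(bad)) stop("unknown section(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(sections = sections,
                 figure_format = match.arg(figure_format), title = title),
            class = "report_spec")
}

#' Render an HTML report from a session state
#'
#' Produces a self-contained HTML document (figures inlined as SVG) with
#' one section per requested analysis view plus a "Session parameters"
#' section printing every parameter value.  Output is deterministic for a
#' given state: two renders differ only in the single timestamp line.
#'
#' @param state A `session_state` from [run_pipeline()] or [load_state()].
#' @param spec A [report_spec()].
#' @param path Output HTML path.
#' @return Invisibly, `path`.
#' @export
render_report <- function(state, spec = report_spec(), path) {
  stopifnot(inherits(state, "session_state"), inherits(spec, "report_spec"))
  needs <- list(
    overview = c("library_sizes", "detected_genes", "sample_distances",
                 "sample_correlation"),
    samples_pca = c("scree_samples", "scores_samples", "hi_loadings"),
    genes_pca = c("scree_genes", "scores_genes", "arrows_genes"),
    pca2go = "enrichment",
    multifactor = "scores_multifactor"
  )
  for (sec in spec$sections) {
    missing <- setdiff(needs[[sec]], names(state$tables))
    if (length(missing)) {
      stop("section '", sec, "' needs uncomputed artifact(s): ",
           paste(missing, collapse = ", "),
           " -- re-run the pipeline with the matching inputs", call. = FALSE)
    }
  }
  tb <- state$tables
  parts <- c(
    "<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\">",
    sprintf("<title>%s</title>", html_escape(spec$title)),
    "<style>",
    "body{font-family:sans-serif;max-width:1000px;margin:2em auto;color:#222}",
    "table{border-collapse:collapse;margin:1em 0;font-size:0.85em}",
    "td,th{border:1px solid #bbb;padding:2px 8px;text-align:right}",
    "th{background:#eee}td:first-child,th:first-child{text-align:left}",
    "h2{border-bottom:2px solid #888;padding-top:1em}",
    ".figure{margin:1em 0}",
    "</style></head><body>",
    sprintf("<h1>%s</h1>", html_escape(spec$title)),
    sprintf("<p id=\"timestamp\">Generated by pcalens %s; session of %s; rendered %s</p>",
            html_escape(state$version), html_escape(state$timestamp),
            format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))
  )

  if ("overview" %in% spec$sections) {
    parts <- c(parts, "<h2>Data overview</h2>",
               "<h3>Library sizes</h3>", df_to_html(tb$library_sizes),
               "<h3>Detected genes</h3>", df_to_html(tb$detected_genes),
               "<h3>Sample distances (Euclidean, transformed data)</h3>",
               df_to_html(tb$sample_distances),
               "<h3>Sample correlation (normalized counts)</h3>",
               df_to_html(tb$sample_correlation))
  }
  if ("samples_pca" %in% spec$sections) {
    parts <- c(parts, "<h2>Samples PCA</h2>",
               report_figures(spec, samples_pca_figures(state)),
               "<h3>Scree</h3>", df_to_html(tb$scree_samples),
               "<h3>Sample scores</h3>", df_to_html(tb$scores_samples),
               "<h3>Genes with highest loadings</h3>",
               df_to_html(tb$hi_loadings))
  }
  if ("genes_pca" %in% spec$sections) {
    parts <- c(parts, "<h2>Genes PCA (biplot)</h2>",
               report_figures(spec, genes_pca_figures(state)),
               "<h3>Scree</h3>", df_to_html(tb$scree_genes),
               "<h3>Gene scores (first rows)</h3>",
               df_to_html(head(tb$scores_genes, 50)),
               "<h3>Sample biplot arrows</h3>", df_to_html(tb$arrows_genes))
  }
  if ("pca2go" %in% spec$sections) {
    parts <- c(parts, "<h2>Functional annotation of components</h2>",
               df_to_html(tb$enrichment))
  }
  if ("multifactor" %in% spec$sections) {
    parts <- c(parts, "<h2>Multifactor PCA</h2>",
               "<h3>Scree</h3>", df_to_html(tb$scree_multifactor),
               "<h3>Scores (first rows)</h3>",
               df_to_html(head(tb$scores_multifactor, 50)))
  }

  parts <- c(parts, "<h2>Session parameters</h2>", params_html(state),
             "</body></html>")
  writeLines(parts, path, useBytes = TRUE)
  invisible(path)
}

params_html <- function(state) {
  p <- state$params
  rows <- vapply(names(p), function(nm) {
    val <- p[[nm]]
    val <- if (is.null(val)) "NULL" else paste(format(val), collapse = ", ")
    sprintf("<tr><td>%s</td><td>%s</td></tr>", html_escape(nm), html_escape(val))
  }, "")
  inp <- vapply(seq_len(nrow(state$inputs)), function(i) {
    sprintf("<tr><td>%s</td><td>%s (md5 %s)</td></tr>",
            html_escape(state$inputs$role[i]),
            html_escape(state$inputs$path[i]),
            html_escape(state$inputs$md5[i]))
  }, "")
  c("<table><tr><th>parameter</th><th>value</th></tr>", rows, inp, "</table>")
}

df_to_html <- function(df, max_rows = 100) {
  df <- as.data.frame(df)
  truncated <- nrow(df) > max_rows
  if (truncated) df <- head(df, max_rows)
  cells <- lapply(df, function(x) {
    if (is.double(x)) ifelse(is.na(x), "NA", sprintf("%.4g", x))
    else ifelse(is.na(x), "NA", as.character(x))
  })
  header <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                                  collapse = ""), "</tr>")
  body <- if (nrow(df)) {
    apply(do.call(cbind, lapply(cells, html_escape)), 1, function(r) {
      paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>")
    })
  } else character(0)
  c("<table>", header, body, "</table>",
    if (truncated) sprintf("<p><em>(first %d rows shown)</em></p>", max_rows))
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# Build ggplot figures for the report from stored tables only, so a loaded
# archive renders identically to the live session.
samples_pca_figures <- function(state) {
  sc <- state$tables$scores_samples
  meta <- state$metadata
  factors <- setdiff(names(meta), "sample_id")
  colour <- if (length(factors)) factors[1] else NULL
  df <- dplyr::left_join(sc, meta, by = c(observation_id = "sample_id"))
  ve <- state$tables$scree_samples$variance_explained
  pts <- if (is.null(colour)) {
    ggplot2::geom_point(size = 3)
  } else {
    ggplot2::geom_point(size = 3, ggplot2::aes(colour = .data[[colour]]))
  }
  p1 <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2)) +
    pts +
    ggplot2::labs(colour = colour,
                  x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * ve[2]),
                  title = "Samples PCA") +
    ggplot2::theme_bw()
  p2 <- plot_scree_df(state$tables$scree_samples, "Scree (samples PCA)")
  list(p1, p2)
}

genes_pca_figures <- function(state) {
  sc <- state$tables$scores_genes
  ar <- state$tables$arrows_genes
  scale_arrows <- max(abs(c(sc$PC1, sc$PC2))) /
    max(abs(c(ar$PC1, ar$PC2, 1e-12)))
  p <- ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_segment(
      data = ar, colour = "firebrick",
      ggplot2::aes(x = 0, y = 0, xend = .data$PC1 * scale_arrows,
                   yend = .data$PC2 * scale_arrows)) +
    ggplot2::geom_text(data = ar, colour = "firebrick", size = 3,
                       ggplot2::aes(x = .data$PC1 * scale_arrows,
                                    y = .data$PC2 * scale_arrows,
                                    label = .data$id)) +
    ggplot2::labs(title = "Genes PCA with sample arrows (biplot)") +
    ggplot2::theme_bw()
  list(p)
}

plot_scree_df <- function(scree_tb, title) {
  ggplot2::ggplot(scree_tb,
                  ggplot2::aes(.data$component, .data$variance_explained)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative)) +
    ggplot2::scale_x_continuous(breaks = scree_tb$component) +
    ggplot2::labs(x = "component", y = "variance explained", title = title) +
    ggplot2::theme_bw()
}

report_figures <- function(spec, plots) {
  if (spec$figure_format == "none") return(character(0))
  unlist(lapply(plots, function(p) {
    c("<div class=\"figure\">", inline_svg(p), "</div>")
  }))
}

# Render a ggplot to inline SVG text.  The cairo SVG device is
# deterministic for identical input, so reports stay byte-reproducible.
inline_svg <- function(p, width = 7, height = 5) {
  f <- tempfile(fileext = ".svg")
  on.exit(unlink(f))
  grDevices::svg(f, width = width, height = height)
  print(p)
  grDevices::dev.off()
  readLines(f, warn = FALSE)
}
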