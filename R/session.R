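# End-to-end pipeline and portable session archive.

default_params <- function() {
  list(
    transform = "vst", pseudocount = 1, ntop = 500, scale = FALSE,
    pcs = NULL, top_fraction = 0.025, min_term_size = 5, max_term_size = 500,
    min_count = 5, min_samples = 1, min_mean = 1,
    n_hi_loadings = 10, multifactor = NULL, seed = 1
  )
}

#' Run the full exploratory pipeline
#'
#' Executes read - bind - size factors - transform - PCA (samples, genes,
#' optional multifactor) - overview summaries - optional GO annotation of
#' the components, and returns a session state holding every parameter and
#' derived table needed to re-render the analysis deterministically.
#'
#' @param config A named list (or path to a flat `key: value` config file,
#'   see [read_config()]) with at least `counts` and `metadata` paths.
#'   Optional keys: `annotation`, `go` (paths), `transform` (`"vst"` or
#'   `"shifted_log"`), `pseudocount`, `ntop`, `scale`, `pcs`,
#'   `top_fraction`, `min_term_size`, `max_term_size`, `min_count`,
#'   `min_samples`, `min_mean`, `n_hi_loadings`, `multifactor` (two factor
#'   names), `seed`.
#' @return An object of class `session_state`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) config <- read_config(config)
  stopifnot(is.list(config))
  if (is.null(config$counts) || is.null(config$metadata)) {
    stop("config must name `counts` and `metadata` paths", call. = FALSE)
  }
  params <- utils::modifyList(default_params(),
                              config[setdiff(names(config),
                                             c("counts", "metadata",
                                               "annotation", "go"))])
  stage <- function(name, expr) {
    log_info("stage %s", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("%s: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  counts <- stage("read_counts", read_counts(config$counts))
  metadata <- stage("read_metadata", read_metadata(config$metadata))
  annotation <- if (!is.null(config$annotation)) {
    stage("read_annotation", read_annotation(config$annotation))
  }
  go <- if (!is.null(config$go)) {
    stage("read_go_annotation", read_go_annotation(config$go))
  }
  bundle <- stage("bind_experiment",
                  bind_experiment(counts, metadata, annotation))

  sf <- stage("estimate_size_factors", estimate_size_factors(bundle$counts))
  trend <- NULL
  if (identical(params$transform, "vst")) {
    trend <- stage("fit_dispersion_trend",
                   fit_dispersion_trend(bundle$counts, sf,
                                        min_mean = params$min_mean))
    transformed <- stage("transform", vst(bundle$counts, sf, trend))
  } else if (identical(params$transform, "shifted_log")) {
    transformed <- stage("transform",
                         shifted_log(bundle$counts, sf,
                                     pseudocount = params$pseudocount))
  } else {
    stop("transform: unknown transform '", params$transform,
         "' (expected vst or shifted_log)", call. = FALSE)
  }
  normalized <- normalize_counts(bundle$counts, sf)

  if (is.null(params$pcs)) params$pcs <- seq_len(min(4, ncol(bundle$counts) - 1))

  pca_s <- stage("pca_samples",
                 pca_samples(transformed, ntop = params$ntop,
                             scale = isTRUE(params$scale)))
  pca_g <- stage("pca_genes", pca_genes(transformed, ntop = params$ntop))
  pca_m <- NULL
  if (!is.null(params$multifactor)) {
    pca_m <- stage("pca_multifactor",
                   pca_multifactor(transformed, bundle$metadata,
                                   params$multifactor[1],
                                   params$multifactor[2],
                                   ntop = params$ntop))
  }

  ov_lib <- stage("library_sizes", library_sizes(bundle$counts))
  ov_det <- stage("detected_genes",
                  detected_genes(bundle$counts, params$min_count,
                                 params$min_samples))
  ov_dist <- stage("sample_distances", sample_distances(transformed))
  ov_cor <- stage("sample_correlation", sample_correlation(normalized))

  enrichment <- NULL
  if (!is.null(go)) {
    pcs_use <- params$pcs[params$pcs <= ncol(pca_s$loadings)]
    enrichment <- stage("pca2go",
                        pca2go_all(pca_s, go, pcs = pcs_use,
                                   top_fraction = params$top_fraction,
                                   min_term_size = params$min_term_size,
                                   max_term_size = params$max_term_size))
  }

  hi <- dplyr::bind_rows(lapply(params$pcs[params$pcs <= ncol(pca_s$loadings)],
    function(pc) {
      h <- hi_loadings(pca_s, pc, params$n_hi_loadings)
      dplyr::bind_rows(
        tibble::tibble(pc = pc, direction = "positive",
                       gene_id = h$positive$gene_id,
                       loading = h$positive$loading),
        tibble::tibble(pc = pc, direction = "negative",
                       gene_id = h$negative$gene_id,
                       loading = h$negative$loading)
      )
    }))

  tables <- list(
    size_factors = tibble::tibble(sample_id = names(sf),
                                  size_factor = as.numeric(sf)),
    library_sizes = ov_lib,
    detected_genes = dplyr::mutate(ov_det$per_sample,
                                   robust_total = ov_det$robust_total),
    sample_distances = mat_to_df(ov_dist$values),
    sample_correlation = mat_to_df(ov_cor),
    scree_samples = scree(pca_s),
    scores_samples = scores_df(pca_s),
    hi_loadings = hi,
    scree_genes = scree(pca_g),
    scores_genes = scores_df(pca_g),
    arrows_genes = mat_to_df(pca_g$arrows)
  )
  if (!is.null(trend)) {
    tables$dispersion_trend <- tibble::tibble(
      a0 = trend$a0, a1 = trend$a1, n_genes_used = trend$n_genes_used)
  }
  if (!is.null(pca_m)) {
    tables$scores_multifactor <- scores_df(pca_m)
    tables$scree_multifactor <- scree(pca_m)
  }
  if (!is.null(enrichment)) {
    tables$enrichment <- tibble::as_tibble(as.data.frame(enrichment))
  }

  inputs <- tibble::tibble(
    role = c("counts", "metadata",
             if (!is.null(config$annotation)) "annotation",
             if (!is.null(config$go)) "go"),
    path = c(config$counts, config$metadata,
             if (!is.null(config$annotation)) config$annotation,
             if (!is.null(config$go)) config$go)
  )
  inputs$md5 <- unname(tools::md5sum(inputs$path))

  structure(
    list(inputs = inputs, params = params, tables = tables,
         metadata = bundle$metadata,
         version = as.character(utils::packageVersion("pcalens")),
         timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    class = "session_state"
  )
}

scores_df <- function(pca) {
  df <- mat_to_df(pca$scores)
  names(df)[1] <- "observation_id"
  df
}

mat_to_df <- function(m) {
  df <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  dplyr::bind_cols(tibble::tibble(id = rownames(m)), df)
}

#' @export
print.session_state <- function(x, ...) {
  cat(sprintf("<session_state> pcalens %s, %s\n", x$version, x$timestamp))
  cat("  tables:", paste(names(x$tables), collapse = ", "), "\n")
  invisible(x)
}

#' Save a session state as a portable archive
#'
#' Writes a single-file archive (tar layout: `manifest.json` plus one TSV
#' per derived table, written at full precision) that [load_state()]
#' restores bit-identically.  The manifest records the tool version,
#' parameters, input digests and a digest per table for corruption
#' detection.
#'
#' @param state A `session_state` from [run_pipeline()].
#' @param path Output archive path (conventionally `.session.tar`).
#' @return Invisibly, `path`.
#' @export
save_state <- function(state, path) {
  stopifnot(inherits(state, "session_state"))
  dir <- tempfile("session")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  files <- character(0)
  for (nm in names(state$tables)) {
    f <- paste0("table_", nm, ".tsv")
    write_table(as.data.frame(state$tables[[nm]]), file.path(dir, f))
    files[nm] <- f
  }
  write_table(as.data.frame(state$metadata), file.path(dir, "metadata.tsv"))
  manifest <- list(
    tool = "pcalens",
    version = state$version,
    timestamp = state$timestamp,
    params = state$params,
    inputs = as.data.frame(state$inputs),
    tables = lapply(names(files), function(nm) {
      list(name = nm, file = files[[nm]],
           md5 = unname(tools::md5sum(file.path(dir, files[[nm]]))))
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  path <- normalizePath(path, mustWork = FALSE)
  old <- setwd(dir)
  on.exit(setwd(old), add = TRUE, after = FALSE)
  utils::tar(path, files = ".", tar = "internal")
  invisible(path)
}

#' Load a session state archive
#'
#' @param path Archive written by [save_state()].
#' @return A `session_state`.
#' @export
load_state <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dir <- tempfile("session")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  utils::untar(path, exdir = dir, tar = "internal")
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("corrupt archive: manifest.json missing", call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  cur_major <- as.integer(strsplit(as.character(utils::packageVersion("pcalens")),
                                   "[.]")[[1]][1])
  arc_major <- as.integer(strsplit(manifest$version, "[.]")[[1]][1])
  if (!is.na(arc_major) && arc_major > cur_major) {
    warning(sprintf("archive written by a newer major version (%s > %s)",
                    manifest$version, utils::packageVersion("pcalens")),
            call. = FALSE)
  }
  tables <- list()
  tab_info <- manifest$tables
  for (i in seq_len(nrow(tab_info))) {
    nm <- tab_info$name[i]
    f <- file.path(dir, tab_info$file[i])
    if (!file.exists(f)) {
      stop("corrupt archive: table '", nm, "' missing", call. = FALSE)
    }
    md5 <- unname(tools::md5sum(f))
    if (!identical(md5, tab_info$md5[i])) {
      stop("corrupt archive: digest mismatch for table '", nm, "'",
           call. = FALSE)
    }
    tables[[nm]] <- read_table(f)
  }
  metadata <- read_table(file.path(dir, "metadata.tsv"))
  params <- manifest$params
  structure(
    list(inputs = tibble::as_tibble(manifest$inputs), params = params,
         tables = tables, metadata = metadata,
         version = manifest$version, timestamp = manifest$timestamp),
    class = "session_state"
  )
}

#' Read a flat key-value config file
#'
#' A minimal YAML-like dialect: one `key: value` pair per line, `#`
#' comments, blank lines ignored.  Values are type-converted (logicals,
#' numbers); comma-separated values become vectors.
#'
#' @param path Path to the config file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE)) {
      stop("malformed config line (expected 'key: value'): ", ln, call. = FALSE)
    }
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    if (grepl(",", val, fixed = TRUE)) {
      val <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    }
    out[[key]] <- type.convert(val, as.is = TRUE)
  }
  out
}
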