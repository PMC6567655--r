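# broom-style tidiers for the package's result objects.

#' Tidy a PCA result
#'
#' @param x A `pca_result`.
#' @param matrix Which quantity to return: `"scores"` (observations x
#'   components, long), `"loadings"` (variables x components, long) or
#'   `"eigenvalues"` (one row per component: variance explained and its
#'   running sum, as in [scree()]).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pca_result
#' @export
tidy.pca_result <- function(x, matrix = c("scores", "loadings", "eigenvalues"),
                            ...) {
  matrix <- match.arg(matrix)
  if (matrix == "eigenvalues") return(scree(x))
  m <- if (matrix == "scores") x$scores else x$loadings
  id_col <- if (matrix == "scores") "observation_id" else "variable_id"
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  out[[id_col]] <- rownames(m)
  tidyr::pivot_longer(out, -dplyr::all_of(id_col),
                      names_to = "component", values_to = "value") |>
    dplyr::mutate(component = as.integer(sub("^PC", "", .data$component))) |>
    dplyr::select(dplyr::all_of(id_col), "component", "value")
}

#' One-row summary of a PCA result
#'
#' @param x A `pca_result`.
#' @param ... Unused.
#' @return A tibble with the observation/variable counts, `ntop`, the
#'   number of components, and the variance explained by the first two.
#' @method glance pca_result
#' @export
glance.pca_result <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    n_observations = length(x$observation_ids),
    n_variables = length(x$variable_ids),
    ntop = x$ntop,
    n_components = length(x$variance_explained),
    var_explained_pc1 = x$variance_explained[1],
    var_explained_pc2 = if (length(x$variance_explained) > 1)
      x$variance_explained[2] else NA_real_
  )
}

#' Tidy a transformed matrix into long format
#'
#' @param x A `transformed_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `sample_id`, `value`.
#' @method tidy transformed_matrix
#' @export
tidy.transformed_matrix <- function(x, ...) {
  m <- x$values
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  out$gene_id <- rownames(m)
  tidyr::pivot_longer(out, -"gene_id", names_to = "sample_id",
                      values_to = "value") |>
    dplyr::select("gene_id", "sample_id", "value")
}

#' Tidy a sample distance object
#'
#' @param x A `sample_dist`.
#' @param ... Unused.
#' @return A tibble with columns `sample_1`, `sample_2`, `distance`.
#' @method tidy sample_dist
#' @export
tidy.sample_dist <- function(x, ...) {
  df <- as.data.frame(as.table(x$values), stringsAsFactors = FALSE)
  names(df) <- c("sample_1", "sample_2", "distance")
  tibble::as_tibble(df)
}

#' One-row summary of a session state
#'
#' @param x A `session_state`.
#' @param ... Unused.
#' @return A tibble with version, timestamp, table count and parameters of
#'   record.
#' @method glance session_state
#' @export
glance.session_state <- function(x, ...) {
  tibble::tibble(
    version = x$version,
    timestamp = x$timestamp,
    n_tables = length(x$tables),
    transform = x$params$transform,
    ntop = x$params$ntop
  )
}
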