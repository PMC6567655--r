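#' Read a raw count matrix from delimited text
#'
#' Reads a genes x samples matrix of read counts from a tab-, comma- or
#' semicolon-separated file with gene IDs in the first column and sample IDs
#' in the header.  When `dialect` is not given the delimiter is detected by
#' trying tab, comma and semicolon in that order and requiring a consistent
#' field count across the header and the first 50 data lines.
#'
#' @param path Path to the text file.
#' @param dialect Optional delimiter, one of `"\t"`, `","`, `";"`.
#'   Auto-detected when `NULL`.
#' @param strict When `TRUE` (default) every entry must be an integer; when
#'   `FALSE` values within `1e-6` of an integer are rounded (some upstream
#'   quantifiers emit fractional expected counts).
#' @return A numeric matrix of counts with gene IDs as rownames and sample
#'   IDs as colnames.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("s1\ts2", "g1\t2\t4", "g2\t4\t8"), tf)
#' read_counts(tf)
#' @export
read_counts <- function(path, dialect = NULL, strict = TRUE) {
  parsed <- read_delimited(path, dialect)
  ids <- parsed$row_ids
  if (anyDuplicated(ids) > 0) {
    stop("duplicate gene ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(parsed$col_ids) > 0) {
    stop("duplicate sample ID(s): ",
         paste(unique(parsed$col_ids[duplicated(parsed$col_ids)]), collapse = ", "),
         call. = FALSE)
  }
  cells <- parsed$cells
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !(cells %in% c("NA", "")), arr.ind = TRUE)
    if (nrow(bad) == 0) bad <- which(is.na(num), arr.ind = TRUE)
    stop(sprintf("non-numeric count '%s' at gene '%s', sample '%s'",
                 cells[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 parsed$col_ids[bad[1, 2]]), call. = FALSE)
  }
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)
    stop(sprintf("negative count %s at gene '%s', sample '%s'",
                 format(num[bad[1, 1], bad[1, 2]]), ids[bad[1, 1]],
                 parsed$col_ids[bad[1, 2]]), call. = FALSE)
  }
  off <- abs(num - round(num))
  tol <- if (strict) 0 else 1e-6
  if (any(off > tol)) {
    bad <- which(off > tol, arr.ind = TRUE)
    stop(sprintf("non-integer count '%s' at gene '%s', sample '%s' (counts must be integral)",
                 cells[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 parsed$col_ids[bad[1, 2]]), call. = FALSE)
  }
  num <- round(num)
  dimnames(num) <- list(ids, parsed$col_ids)
  log_info("read_counts: %d genes x %d samples from %s", nrow(num), ncol(num), path)
  num
}

#' Read a sample metadata table
#'
#' Reads a samples x factors table with sample IDs in the first column.  All
#' remaining columns become experimental factors (kept as character);
#' all-blank columns are dropped with a warning.
#'
#' @inheritParams read_counts
#' @return A tibble with a `sample_id` column followed by one column per
#'   experimental factor.
#' @export
read_metadata <- function(path, dialect = NULL) {
  parsed <- read_delimited(path, dialect)
  ids <- parsed$row_ids
  if (anyDuplicated(ids) > 0) {
    stop("duplicate sample ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  cells <- parsed$cells
  keep <- apply(cells, 2, function(x) any(!is.na(x) & trimws(x) != ""))
  if (length(keep) && any(!keep)) {
    warning("dropping all-blank factor column(s): ",
            paste(parsed$col_ids[!keep], collapse = ", "), call. = FALSE)
    log_info("read_metadata: dropped blank column(s) %s",
             paste(parsed$col_ids[!keep], collapse = ", "))
  }
  out <- tibble::tibble(sample_id = ids)
  for (j in which(keep)) {
    v <- cells[, j]
    v[!is.na(v) & trimws(v) == ""] <- NA_character_
    out[[parsed$col_ids[j]]] <- v
  }
  out
}

#' Read a gene annotation table
#'
#' A table mapping the primary gene IDs of the count matrix to alternative
#' identifiers (symbols, secondary accessions).  First column is the primary
#' ID; remaining columns are alternative ID types.  Lookup elsewhere in the
#' package is exact-match and case-sensitive.
#'
#' @inheritParams read_counts
#' @return A tibble with a `gene_id` column plus one column per ID type.
#' @export
read_annotation <- function(path, dialect = NULL) {
  parsed <- read_delimited(path, dialect)
  ids <- parsed$row_ids
  if (anyDuplicated(ids) > 0) {
    stop("duplicate primary gene ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(gene_id = ids)
  for (j in seq_along(parsed$col_ids)) out[[parsed$col_ids[j]]] <- parsed$cells[, j]
  out
}

#' Combine counts, metadata and annotation into an experiment bundle
#'
#' Samples present in both the count matrix and the metadata are kept and
#' reordered to the count-matrix order (counts are the primary object);
#' samples present in exactly one of the two are dropped with a warning.
#'
#' @param counts Count matrix as returned by [read_counts()].
#' @param metadata Sample metadata tibble as returned by [read_metadata()].
#' @param annotation Optional gene annotation tibble ([read_annotation()]).
#' @return An object of class `experiment_bundle`: a list with elements
#'   `counts`, `metadata` and `annotation`.
#' @export
bind_experiment <- function(counts, metadata, annotation = NULL) {
  check_counts(counts)
  stopifnot(is.data.frame(metadata), "sample_id" %in% names(metadata))
  common <- intersect(colnames(counts), metadata$sample_id)
  if (length(common) == 0) {
    stop("no overlapping samples between counts and metadata", call. = FALSE)
  }
  only_counts <- setdiff(colnames(counts), common)
  only_meta <- setdiff(metadata$sample_id, common)
  if (length(only_counts) || length(only_meta)) {
    warning("samples present in only one input dropped: ",
            paste(c(only_counts, only_meta), collapse = ", "), call. = FALSE)
  }
  keep <- colnames(counts)[colnames(counts) %in% common]
  counts <- counts[, keep, drop = FALSE]
  metadata <- metadata[match(keep, metadata$sample_id), , drop = FALSE]
  if (!is.null(annotation)) {
    stopifnot(is.data.frame(annotation), "gene_id" %in% names(annotation))
    annotation <- tibble::as_tibble(annotation)
  }
  structure(
    list(counts = counts, metadata = tibble::as_tibble(metadata),
         annotation = annotation),
    class = "experiment_bundle"
  )
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(sprintf("<experiment_bundle> %d genes x %d samples; factors: %s%s\n",
              nrow(x$counts), ncol(x$counts),
              paste(setdiff(names(x$metadata), "sample_id"), collapse = ", "),
              if (is.null(x$annotation)) "" else "; with gene annotation"))
  invisible(x)
}

#' Read gene-to-GO-term annotation
#'
#' Supports a plain two-column TSV of `(gene_id, go_id)` pairs, or the GAF
#' 2.x format (columns 2 = object ID and 5 = GO ID; `!` comment lines
#' skipped).  Term IDs must match `GO:` followed by seven digits.
#'
#' @param path Path to the annotation file.
#' @param format `"two_column_tsv"` or `"gaf"`.
#' @param namespace GO namespace label attached to the object
#'   (`"BP"`, `"MF"` or `"CC"`).
#' @return An object of class `go_annotation`: list with `term_to_genes`
#'   (named list of gene ID vectors), `term_names` and `namespace`.
#' @export
read_go_annotation <- function(path, format = c("two_column_tsv", "gaf"),
                               namespace = c("BP", "MF", "CC")) {
  format <- match.arg(format)
  namespace <- match.arg(namespace)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  if (format == "gaf") {
    keep <- !startsWith(lines, "!") & nzchar(lines)
    lines <- lines[keep]; lineno <- lineno[keep]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- vapply(fields, length, 1L) < 5
    if (any(short)) {
      stop(sprintf("GAF line %d has fewer than 5 columns", lineno[short][1]), call. = FALSE)
    }
    genes <- vapply(fields, `[[`, "", 2L)
    terms <- vapply(fields, `[[`, "", 5L)
  } else {
    keep <- nzchar(lines) & !startsWith(lines, "#")
    lines <- lines[keep]; lineno <- lineno[keep]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- vapply(fields, length, 1L) < 2
    if (any(short)) {
      stop(sprintf("line %d does not have two tab-separated columns", lineno[short][1]),
           call. = FALSE)
    }
    genes <- vapply(fields, `[[`, "", 1L)
    terms <- vapply(fields, `[[`, "", 2L)
  }
  bad <- !grepl("^GO:[0-9]{7}$", terms)
  if (any(bad)) {
    stop(sprintf("malformed GO ID '%s' on line %d", terms[bad][1], lineno[bad][1]),
         call. = FALSE)
  }
  term_to_genes <- lapply(split(genes, terms), function(g) sort(unique(g)))
  go_annotation(term_to_genes, namespace = namespace)
}

#' Construct a GO annotation object
#'
#' @param term_to_genes Named list mapping GO term IDs to character vectors
#'   of gene IDs; every set must be non-empty.
#' @param term_names Optional named character vector of term labels.
#' @param namespace GO namespace (`"BP"`, `"MF"` or `"CC"`).
#' @return A `go_annotation` object.
#' @export
go_annotation <- function(term_to_genes, term_names = NULL,
                          namespace = c("BP", "MF", "CC")) {
  namespace <- match.arg(namespace)
  stopifnot(is.list(term_to_genes), !is.null(names(term_to_genes)))
  ids <- names(term_to_genes)
  bad <- !grepl("^GO:[0-9]{7}$", ids)
  if (any(bad)) stop("malformed GO ID(s): ", paste(ids[bad], collapse = ", "), call. = FALSE)
  if (any(vapply(term_to_genes, length, 1L) == 0)) {
    stop("every GO term must annotate at least one gene", call. = FALSE)
  }
  if (is.null(term_names)) {
    term_names <- setNames(ids, ids)
  } else {
    term_names <- setNames(as.character(term_names[ids]), ids)
    term_names[is.na(term_names)] <- ids[is.na(term_names)]
  }
  structure(list(term_to_genes = term_to_genes, term_names = term_names,
                 namespace = namespace),
            class = "go_annotation")
}

#' @export
print.go_annotation <- function(x, ...) {
  cat(sprintf("<go_annotation> %d %s terms over %d genes\n",
              length(x$term_to_genes), x$namespace,
              length(unique(unlist(x$term_to_genes, use.names = FALSE)))))
  invisible(x)
}

#' Export a table as TSV at full precision
#'
#' Writes any tabular result (data frame or labelled matrix) as
#' tab-separated UTF-8 text with a header row.  Floating-point values are
#' written with enough digits (`%.17g`) that re-reading reproduces them
#' bit-identically; missing values are written as `NA`.  Matrices are
#' written with their rownames as a leading `id` column.
#'
#' @param table A data frame or matrix.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(table, path) {
  if (is.matrix(table)) {
    df <- as.data.frame(table, check.names = FALSE)
    if (!is.null(rownames(table))) df <- cbind(id = rownames(table), df)
    table <- df
  }
  stopifnot(is.data.frame(table))
  cols <- lapply(table, format_full)
  header <- paste(names(table), collapse = "\t")
  if (nrow(table) == 0) {
    body <- character(0)
  } else {
    body <- do.call(paste, c(cols, sep = "\t"))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

format_full <- function(x) {
  out <- if (is.double(x)) {
    ifelse(is.na(x), "NA",
           ifelse(x == floor(x) & abs(x) < 1e15,
                  sprintf("%.0f", x), sprintf("%.17g", x)))
  } else if (is.logical(x) || is.integer(x)) {
    ifelse(is.na(x), "NA", as.character(x))
  } else {
    ifelse(is.na(x), "NA", as.character(x))
  }
  out
}

#' Read back a table written by [write_table()]
#'
#' @param path Path to a TSV file with a header row.
#' @return A tibble with column types restored (`NA` parsed as missing).
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty file: ", path, call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  out <- vector("list", length(header))
  names(out) <- header
  if (length(lines) == 1) {
    for (j in seq_along(header)) out[[j]] <- character(0)
    return(tibble::as_tibble(out))
  }
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  n_fields <- vapply(fields, length, 1L)
  if (any(n_fields != length(header))) {
    stop(sprintf("line %d has %d fields, expected %d",
                 which(n_fields != length(header))[1] + 1L,
                 n_fields[n_fields != length(header)][1], length(header)),
         call. = FALSE)
  }
  m <- matrix(unlist(fields, use.names = FALSE), ncol = length(header), byrow = TRUE)
  for (j in seq_along(header)) {
    out[[j]] <- type.convert(m[, j], as.is = TRUE, na.strings = "NA")
  }
  tibble::as_tibble(out)
}

# Shared delimited-text reader: detects the dialect when not given, returns
# row IDs (first column), column IDs (header) and a character cell matrix.
read_delimited <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("file has no data rows: ", path, call. = FALSE)
  if (is.null(dialect)) {
    dialect <- detect_dialect(lines)
  } else if (!dialect %in% c("\t", ",", ";")) {
    stop("dialect must be one of tab, comma, semicolon", call. = FALSE)
  }
  header <- split_fields(lines[1], dialect)[[1]]
  fields <- split_fields(lines[-1], dialect)
  n_fields <- vapply(fields, length, 1L)
  nf <- n_fields[1]
  if (any(n_fields != nf)) {
    stop(sprintf("inconsistent field count on data line %d",
                 which(n_fields != nf)[1] + 1L), call. = FALSE)
  }
  # Header may either name every field or omit the leading row-ID cell
  # (R's write.table convention).
  if (length(header) == nf) {
    col_ids <- header[-1]
  } else if (length(header) == nf - 1L) {
    col_ids <- header
  } else {
    stop(sprintf("header has %d fields but data lines have %d",
                 length(header), nf), call. = FALSE)
  }
  row_ids <- vapply(fields, `[[`, "", 1L)
  cells <- matrix(NA_character_, nrow = length(fields), ncol = nf - 1L)
  if (nf > 1) {
    cells <- matrix(unlist(lapply(fields, `[`, -1L), use.names = FALSE),
                    ncol = nf - 1L, byrow = TRUE)
  }
  cells[] <- unquote_ids(cells)
  list(row_ids = unquote_ids(row_ids), col_ids = unquote_ids(col_ids),
       cells = cells)
}

unquote_ids <- function(x) gsub('^"|"$', "", x)

# strsplit drops trailing empty fields; pad with a sentinel so blank
# trailing cells survive.
split_fields <- function(lines, delim) {
  parts <- strsplit(paste0(lines, "\x01"), delim, fixed = TRUE)
  lapply(parts, function(x) {
    x[length(x)] <- sub("\x01$", "", x[length(x)])
    x
  })
}

detect_dialect <- function(lines) {
  probe <- lines[seq_len(min(length(lines), 51L))]
  for (cand in c("\t", ",", ";")) {
    nf <- vapply(split_fields(probe, cand), length, 1L)
    data_nf <- nf[-1]
    if (length(unique(data_nf)) == 1 && data_nf[1] >= 2 &&
        nf[1] %in% c(data_nf[1], data_nf[1] - 1L)) {
      return(cand)
    }
  }
  stop("could not detect delimiter (tried tab, comma, semicolon)", call. = FALSE)
}
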