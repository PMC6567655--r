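# Internal helpers shared across modules.

log_info <- function(fmt, ...) {
  if (isTRUE(getOption("pcalens.verbose", TRUE))) {
    message("[INFO] ", sprintf(fmt, ...))
  }
  invisible(NULL)
}

# Counts must arrive as a labelled numeric matrix with non-negative entries.
check_counts <- function(counts, arg = "counts") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop(sprintf("`%s` must be a numeric matrix (genes x samples)", arg), call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop(sprintf("`%s` must carry gene IDs as rownames and sample IDs as colnames", arg),
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts)) > 0) {
    stop(sprintf("duplicate gene IDs in `%s`", arg), call. = FALSE)
  }
  if (anyDuplicated(colnames(counts)) > 0) {
    stop(sprintf("duplicate sample IDs in `%s`", arg), call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop(sprintf("`%s` must be finite and non-negative", arg), call. = FALSE)
  }
  invisible(counts)
}

# Row variances without matrixStats; stable and vectorised.
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
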