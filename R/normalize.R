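#' Median-of-ratios size factors
#'
#' Per-sample scaling constants making counts comparable across sequencing
#' depths, computed by the median-of-ratios method: for sample j,
#' `s_j = median_i( count_ij / geomean_i )` over the genes whose geometric
#' mean across samples is strictly positive (i.e. genes with no zero count).
#' This is robust under the assumption that most genes are not
#' differentially expressed.
#'
#' @param counts Numeric count matrix (genes x samples) with dimnames.
#' @return An object of class `size_factors`: a named numeric vector of
#'   positive per-sample factors with a `method` attribute.
#' @examples
#' m <- matrix(c(2, 4, 6, 4, 8, 12), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' estimate_size_factors(m)  # (1/sqrt(2), sqrt(2))
#' @export
estimate_size_factors <- function(counts) {
  check_counts(counts)
  if (ncol(counts) == 1) {
    warning("single sample: size factor set to 1", call. = FALSE)
    sf <- setNames(1, colnames(counts))
    return(structure(sf, method = "median_of_ratios", class = "size_factors"))
  }
  usable <- rowSums(counts == 0) == 0
  if (!any(usable)) {
    stop("no gene has strictly positive counts in every sample; ",
         "filter genes or add a pseudocount before normalization",
         call. = FALSE)
  }
  lg <- log(counts[usable, , drop = FALSE])
  log_geomean <- rowMeans(lg)
  sf <- apply(lg, 2, function(x) exp(median(x - log_geomean)))
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    stop("size-factor estimation produced non-positive values", call. = FALSE)
  }
  log_info("estimate_size_factors: %d usable genes, factors in [%.3g, %.3g]",
           sum(usable), min(sf), max(sf))
  structure(setNames(sf, colnames(counts)),
            method = "median_of_ratios", class = "size_factors")
}

#' @export
print.size_factors <- function(x, ...) {
  cat(sprintf("<size_factors> method: %s\n", attr(x, "method")))
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Normalize counts by size factors
#'
#' Divides each sample column by its size factor.
#'
#' @inheritParams estimate_size_factors
#' @param sf Size factors from [estimate_size_factors()] (or any positive
#'   numeric vector, one per sample).
#' @return A numeric matrix of normalized counts, same shape and labels.
#' @export
normalize_counts <- function(counts, sf) {
  check_counts(counts)
  sf <- as.numeric(sf)
  if (length(sf) != ncol(counts)) {
    stop("length(sf) must equal the number of samples", call. = FALSE)
  }
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    stop("size factors must be positive and finite", call. = FALSE)
  }
  sweep(counts, 2, sf, "/")
}

# Transformed-matrix container: values on a log2-like scale plus provenance.
new_transformed <- function(values, method, params, sf) {
  structure(
    list(values = values, method = method, params = params,
         size_factors = sf),
    class = "transformed_matrix"
  )
}

#' Wrap a plain matrix as a transformed matrix
#'
#' Utility for feeding already-transformed values (e.g. from another tool)
#' into the PCA and overview stages.
#'
#' @param values Numeric matrix (genes x samples) with dimnames.
#' @param method Label recorded as the transformation method.
#' @return A `transformed_matrix` object.
#' @export
as_transformed <- function(values, method = "external") {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry gene and sample IDs as dimnames", call. = FALSE)
  }
  new_transformed(values, method, list(), NULL)
}

#' @export
print.transformed_matrix <- function(x, ...) {
  cat(sprintf("<transformed_matrix> %d genes x %d samples; method: %s\n",
              nrow(x$values), ncol(x$values), x$method))
  invisible(x)
}

#' @export
as.matrix.transformed_matrix <- function(x, ...) x$values

#' @export
dim.transformed_matrix <- function(x) dim(x$values)

# Accept either a transformed_matrix or a plain labelled matrix.
tm_values <- function(transformed) {
  if (inherits(transformed, "transformed_matrix")) return(transformed$values)
  if (is.matrix(transformed) && is.numeric(transformed)) return(transformed)
  stop("expected a transformed_matrix (see shifted_log(), vst(), as_transformed())",
       call. = FALSE)
}

# Subset a transformed matrix by sample, keeping provenance.
tm_subset_samples <- function(transformed, keep) {
  if (inherits(transformed, "transformed_matrix")) {
    out <- transformed
    out$values <- transformed$values[, keep, drop = FALSE]
    if (!is.null(out$size_factors)) {
      out$size_factors <- out$size_factors[keep]
    }
    out
  } else {
    transformed[, keep, drop = FALSE]
  }
}

#' Shifted log transformation
#'
#' `log2(count / size_factor + pseudocount)`: a simple variance-reducing
#' transform using a small positive pseudocount.
#'
#' @inheritParams normalize_counts
#' @param pseudocount Positive constant added before taking log2 (default 1).
#' @return A `transformed_matrix` with method `"shifted_log"`.
#' @export
shifted_log <- function(counts, sf, pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0) {
    stop("`pseudocount` must be a single positive number", call. = FALSE)
  }
  norm <- normalize_counts(counts, sf)
  new_transformed(log2(norm + pseudocount), "shifted_log",
                  list(pseudocount = pseudocount), sf)
}

#' Fit a dispersion-mean trend
#'
#' Fits the parametric dispersion trend `disp(mu) = a0 + a1/mu` of the
#' negative binomial model (`var = mu + disp * mu^2`) to per-gene
#' method-of-moments dispersion estimates on normalized counts:
#' `d_i = max((var_i - mu_i) / mu_i^2, 1e-8)`.  The trend is fitted by
#' ordinary least squares of `d_i` on `(1, 1/mu_i)` over genes with
#' `mu_i > min_mean`, followed by one round of outlier trimming (genes with
#' absolute residual above twice the MAD of the residuals are dropped) and a
#' refit.  `a0` is clamped to at least `1e-8` and `a1` to at least 0.
#'
#' This moment-based fit is a deliberately self-contained approximation to
#' the gamma-family GLM trend fits used by dedicated differential-expression
#' engines; see the package vignette for its accuracy envelope.
#'
#' @inheritParams normalize_counts
#' @param min_mean Genes with normalized mean at or below this value are
#'   excluded from the fit (default 1); near-zero means give unstable
#'   moment dispersions.
#' @return An object of class `dispersion_trend`: list with `a0`, `a1` and
#'   `n_genes_used`.
#' @export
fit_dispersion_trend <- function(counts, sf, min_mean = 1) {
  check_counts(counts)
  if (ncol(counts) < 2) stop("at least 2 samples are required", call. = FALSE)
  norm <- normalize_counts(counts, sf)
  mu <- rowMeans(norm)
  v <- row_vars(norm)
  d <- pmax((v - mu) / mu^2, 1e-8)
  eligible <- is.finite(d) & mu > min_mean
  if (sum(eligible) < 10) {
    stop("fewer than 10 genes with normalized mean above `min_mean`; ",
         "the dispersion trend cannot be fitted -- consider shifted_log() instead",
         call. = FALSE)
  }
  ls_fit <- function(keep) {
    X <- cbind(1, 1 / mu[keep])
    coef <- qr.solve(X, d[keep])
    list(coef = coef, resid = as.numeric(d[keep] - X %*% coef))
  }
  f1 <- ls_fit(eligible)
  cut <- 2 * mad(f1$resid)
  keep2 <- eligible
  keep2[eligible][abs(f1$resid) > cut] <- FALSE
  if (sum(keep2) < 10) keep2 <- eligible  # degenerate trim: keep the full fit set
  f2 <- ls_fit(keep2)
  a0 <- max(f2$coef[1], 1e-8)
  a1 <- max(f2$coef[2], 0)
  log_info("fit_dispersion_trend: a0 = %.4g, a1 = %.4g on %d genes",
           a0, a1, sum(keep2))
  structure(list(a0 = a0, a1 = a1, n_genes_used = sum(keep2)),
            class = "dispersion_trend")
}

#' Construct a dispersion trend by hand
#'
#' Wraps externally estimated trend parameters (e.g. from a GLM-based
#' fitter) for use with [vst()].
#'
#' @param a0 Asymptotic dispersion at large means (> 0).
#' @param a1 Extra-Poisson term (>= 0); disp(mu) = a0 + a1/mu.
#' @param n_genes_used Optional number of genes behind the estimate.
#' @return A `dispersion_trend` object.
#' @export
dispersion_trend <- function(a0, a1, n_genes_used = NA_integer_) {
  stopifnot(is.numeric(a0), length(a0) == 1, a0 > 0,
            is.numeric(a1), length(a1) == 1, a1 >= 0)
  structure(list(a0 = a0, a1 = a1, n_genes_used = as.integer(n_genes_used)),
            class = "dispersion_trend")
}

#' @export
print.dispersion_trend <- function(x, ...) {
  cat(sprintf("<dispersion_trend> disp(mu) = %.4g + %.4g/mu (fit on %d genes)\n",
              x$a0, x$a1, x$n_genes_used))
  invisible(x)
}

#' Variance-stabilizing transformation
#'
#' Closed-form VST for negative-binomial counts under the fitted dispersion
#' trend `disp(mu) = a0 + a1/mu`: with `q = count / size_factor`,
#' \deqn{vst(q) = \log_2\frac{1 + a_1 + 2 a_0 q + 2\sqrt{a_0 q (1 + a_1 + a_0 q)}}{4 a_0}.}
#' The map is strictly increasing in `q`, finite for `q >= 0`, and
#' asymptotically parallel to `log2(q)` for large counts.
#'
#' @inheritParams normalize_counts
#' @param trend A `dispersion_trend` from [fit_dispersion_trend()].
#' @return A `transformed_matrix` with method `"vst"`.
#' @export
vst <- function(counts, sf, trend) {
  if (!inherits(trend, "dispersion_trend")) {
    stop("`trend` must be a dispersion_trend (see fit_dispersion_trend())",
         call. = FALSE)
  }
  norm <- normalize_counts(counts, sf)
  new_transformed(vst_values(norm, trend$a0, trend$a1), "vst",
                  list(a0 = trend$a0, a1 = trend$a1), sf)
}

# The closed-form map itself, on normalized counts q >= 0.
vst_values <- function(q, a0, a1) {
  log2((1 + a1 + 2 * a0 * q + 2 * sqrt(a0 * q * (1 + a1 + a0 * q))) / (4 * a0))
}
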