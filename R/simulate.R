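#' Describe a synthetic RNA-seq experiment
#'
#' The stated world for the package's simulators: a negative-binomial count
#' matrix with planted group structure.  Gene means are log-normal
#' (defaults emulate robustly expressed genes: median around 150 counts,
#' central 95\% range roughly 20-1100) and per-gene dispersions follow the
#' trend `disp(mu) = a0 + a1/mu`.  A fraction of genes carries a planted
#' log2 fold-change between the levels of the first factor; for two-factor
#' designs the affected genes are split evenly between a factor1 main
#' effect, a factor2 main effect, and a factor1 x factor2 interaction.
#'
#' @param n_genes Number of genes (default 2000).
#' @param samples_per_group Samples per factor-level combination (default 6).
#' @param factor_levels Integer vector of level counts: one entry for a
#'   single-factor design (default 2), two entries for a two-factor design.
#' @param frac_affected Fraction of genes with a planted effect (default 0.1).
#' @param lfc Absolute log2 fold-change of planted effects (default 2);
#'   signs are random per gene.
#' @param meanlog,sdlog Log-normal parameters of the gene mean distribution
#'   (defaults `log(150)` and 1).
#' @param a0,a1 Dispersion trend parameters (defaults 0.1 and 5).
#' @param lib_multipliers Optional per-sample library-size multipliers
#'   (default: all 1).
#' @param seed Mandatory RNG seed.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n_genes = 2000, samples_per_group = 6,
                              factor_levels = 2, frac_affected = 0.1,
                              lfc = 2, meanlog = log(150), sdlog = 1,
                              a0 = 0.1, a1 = 5, lib_multipliers = NULL,
                              seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(n_genes >= 1, samples_per_group >= 1,
            length(factor_levels) %in% c(1, 2), all(factor_levels >= 1),
            frac_affected >= 0, frac_affected <= 1, lfc >= 0,
            sdlog >= 0, a0 > 0, a1 >= 0)
  n_samples <- samples_per_group * prod(factor_levels)
  if (!is.null(lib_multipliers)) {
    stopifnot(length(lib_multipliers) == n_samples, all(lib_multipliers > 0))
  } else {
    lib_multipliers <- rep(1, n_samples)
  }
  structure(
    list(n_genes = n_genes, samples_per_group = samples_per_group,
         factor_levels = factor_levels, frac_affected = frac_affected,
         lfc = lfc, meanlog = meanlog, sdlog = sdlog, a0 = a0, a1 = a1,
         lib_multipliers = lib_multipliers, seed = as.integer(seed)),
    class = "simulation_design"
  )
}

#' Simulate a count matrix with planted structure
#'
#' Draws `count[i, j] ~ NB(mean = s_j * mu_i * 2^(effect_ij),
#' dispersion = a0 + a1/mu_i)` under the design, where `effect_ij` encodes
#' the planted fold-changes, and returns both the experiment bundle and a
#' truth record (affected genes with signed log2 fold-changes and effect
#' type, plus per-sample group labels and true library multipliers).
#' Deterministic given the design seed; the caller's RNG state is left
#' untouched.
#'
#' @param design A `simulation_design`.
#' @return A list with `bundle` (an `experiment_bundle`) and `truth` (list
#'   of tibbles `genes` and `samples`).
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  with_seed(design$seed, {
    two_factor <- length(design$factor_levels) == 2
    l1 <- LETTERS[seq_len(design$factor_levels[1])]
    l2 <- if (two_factor) letters[seq_len(design$factor_levels[2])] else NULL
    if (two_factor) {
      combos <- expand.grid(f2 = l2, f1 = l1, stringsAsFactors = FALSE)
      f1 <- rep(combos$f1, each = design$samples_per_group)
      f2 <- rep(combos$f2, each = design$samples_per_group)
    } else {
      f1 <- rep(l1, each = design$samples_per_group)
      f2 <- NULL
    }
    n_samples <- length(f1)
    sample_ids <- sprintf("sample%02d", seq_len(n_samples))
    gene_ids <- sprintf("gene%04d", seq_len(design$n_genes))

    mu <- rlnorm(design$n_genes, design$meanlog, design$sdlog)
    disp <- design$a0 + design$a1 / mu
    n_aff <- round(design$frac_affected * design$n_genes)
    affected <- sort(sample.int(design$n_genes, n_aff))
    beta <- rep(0, design$n_genes)
    beta[affected] <- design$lfc * sample(c(-1, 1), n_aff, replace = TRUE)
    effect_type <- rep("none", design$n_genes)
    if (two_factor && n_aff > 0) {
      # Split planted genes: factor1 main, factor2 main, interaction.
      grp <- rep_len(c("factor1", "factor2", "interaction"), n_aff)
      effect_type[affected] <- grp
    } else {
      effect_type[affected] <- "factor1"
    }

    # Design codes: contrast of the second level against the first.
    x1 <- as.numeric(f1 == l1[min(2, length(l1))] & length(l1) > 1)
    x2 <- if (two_factor && length(l2) > 1) as.numeric(f2 == l2[2]) else rep(0, n_samples)
    log2fc <- matrix(0, design$n_genes, n_samples)
    for (i in affected) {
      xi <- switch(effect_type[i],
                   factor1 = x1, factor2 = x2, interaction = x1 * x2)
      log2fc[i, ] <- beta[i] * xi
    }
    mean_mat <- outer(mu, design$lib_multipliers) * 2^log2fc
    counts <- matrix(
      rnbinom(length(mean_mat), mu = mean_mat,
              size = rep(1 / disp, n_samples)),
      nrow = design$n_genes,
      dimnames = list(gene_ids, sample_ids)
    )
    metadata <- tibble::tibble(sample_id = sample_ids, condition = f1)
    if (two_factor) metadata$batch <- f2
    truth_genes <- tibble::tibble(
      gene_id = gene_ids,
      mean = mu,
      dispersion = disp,
      affected = seq_len(design$n_genes) %in% affected,
      lfc = beta,
      effect_type = effect_type
    )
    truth_samples <- tibble::tibble(
      sample_id = sample_ids,
      condition = f1,
      lib_multiplier = design$lib_multipliers
    )
    if (two_factor) truth_samples$batch <- f2
    list(bundle = bind_experiment(counts, metadata),
         truth = list(genes = truth_genes, samples = truth_samples))
  })
}

#' Simulate a GO annotation with one planted term
#'
#' Generates `n_terms` random GO terms with sizes log-uniform in [5, 200];
#' the first term (`GO:0000001`) is the planted one: its gene set overlaps
#' the `affected` set at the stated fraction (size equal to `|affected|`,
#' with `round(planted_overlap * |affected|)` genes drawn from `affected`
#' and the remainder from the other genes).  Deterministic given the seed.
#'
#' @param genes Character vector of all gene IDs (the annotation universe).
#' @param affected Character vector of planted-signal gene IDs
#'   (subset of `genes`).
#' @param n_terms Number of terms to generate (default 50).
#' @param planted_overlap Fraction of the planted term drawn from
#'   `affected`, in [0, 1] (default 1).
#' @param seed Mandatory RNG seed.
#' @return A `go_annotation`; the planted term ID is attached as attribute
#'   `planted_term`.
#' @export
simulate_go <- function(genes, affected, n_terms = 50, planted_overlap = 1,
                        seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(all(affected %in% genes), n_terms >= 1,
            planted_overlap >= 0, planted_overlap <= 1)
  with_seed(seed, {
    size_p <- length(affected)
    k_in <- round(planted_overlap * size_p)
    others <- setdiff(genes, affected)
    if (size_p - k_in > length(others)) {
      stop("planted overlap infeasible: not enough genes outside `affected`",
           call. = FALSE)
    }
    planted <- c(sample(affected, k_in),
                 if (size_p - k_in > 0) sample(others, size_p - k_in))
    term_ids <- sprintf("GO:%07d", seq_len(n_terms))
    sizes <- pmin(round(exp(runif(n_terms, log(5), log(200)))), length(genes))
    term_to_genes <- lapply(sizes, function(s) sort(sample(genes, s)))
    names(term_to_genes) <- term_ids
    term_to_genes[[term_ids[1]]] <- sort(planted)
    term_names <- setNames(
      c("planted term", sprintf("synthetic term %d", seq_len(n_terms - 1))),
      term_ids
    )
    out <- go_annotation(term_to_genes, term_names, namespace = "BP")
    attr(out, "planted_term") <- term_ids[1]
    out
  })
}
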