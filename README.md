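# pcalens

Exploratory principal component analysis for RNA-seq count data, as a
scriptable library and command line tool.

After read counting, an RNA-seq experiment is a genes × samples matrix of
non-negative integers plus a table of experimental factors.  Before any
differential testing, that matrix needs exploration: are the libraries
comparable, do replicates cluster, which samples are outliers, which genes
drive the main axes of variation, and do those genes share biological
function?  pcalens packages that workflow — normally done interactively —
as deterministic, composable functions whose outputs are tibbles, so the
whole analysis can be scripted, archived and re-rendered exactly.

It is aimed at bioinformaticians and analysts who want the exploratory
step of a bulk (or preprocessed single-cell) RNA-seq workflow to be
reproducible: every figure in the HTML report is recomputed from tables
stored in a portable session archive.

## What it computes

- **Size factors** by the median-of-ratios method: for sample *j*,
  *s<sub>j</sub>* = median<sub>i</sub>( *k<sub>ij</sub>* /
  (∏<sub>v</sub> *k<sub>iv</sub>*)<sup>1/m</sup> ) over genes with no zero
  count, the robust normalization used throughout count-based
  transcriptomics.
- **Variance-reducing transformations**: the shifted log
  log₂(*k*/*s* + pseudocount), and a closed-form **variance-stabilizing
  transformation** for negative-binomial counts whose dispersion follows a
  fitted mean trend disp(μ) = *a₀* + *a₁*/μ (per-gene method-of-moments
  dispersions, trimmed least squares for the trend):

  vst(q) = log₂[ (1 + a₁ + 2a₀q + 2√(a₀q(1 + a₁ + a₀q))) / (4a₀) ]

- **PCA** of samples and of genes over the *ntop* most-variable genes,
  with scree tables, deterministic sign conventions, high-loading gene
  extraction per component and direction, outlier-removal re-projection,
  correlation-biplot sample arrows, rectangle gene selection, profile
  data, and a two-factor stacked PCA.
- **Overview statistics**: library sizes, robustly detected genes,
  Euclidean sample distances with average-linkage clustering order,
  sample correlation matrices, and per-gene grouped summaries.
- **Functional annotation of components**: for each PC and direction, the
  genes in the extreme loading quantile are tested for GO term
  over-representation with the one-sided hypergeometric tail
  P(X ≥ k | N, K, n), Benjamini–Hochberg corrected.
- **Simulators** for negative-binomial counts with planted structure and
  GO annotations with a planted enriched term, used by the test suite.
- **Session archive and HTML report**: `run_pipeline()` records every
  parameter and derived table; `save_state()`/`load_state()` round-trip
  them bit-identically; `render_report()` produces a self-contained HTML
  document that is byte-identical across renders except for one
  timestamp line.

## Worked example

```r
library(pcalens)

sim    <- simulate_counts(simulation_design(seed = 42))
bundle <- sim$bundle
bundle
#> <experiment_bundle> 2000 genes x 12 samples; factors: condition

sf    <- estimate_size_factors(bundle$counts)
trend <- fit_dispersion_trend(bundle$counts, sf)
trend
#> <dispersion_trend> disp(mu) = 0.1032 + 4.487/mu (fit on 1679 genes)

v   <- vst(bundle$counts, sf, trend)
pca <- pca_samples(v, ntop = 500)
pca
#> <pca_result> kind: samples; 12 observations x 500 variables (ntop = 500)
#>   variance explained: PC1 52.7%, PC2 5.8%, PC3 5.4%, PC4 5.2%, PC5 5.0% ...

head(scree(pca), 3)
#> # A tibble: 3 x 3
#>   component variance_explained cumulative
#>       <int>              <dbl>      <dbl>
#> 1         1             0.527       0.527
#> 2         2             0.0581      0.585
#> 3         3             0.0540      0.640

hi_loadings(pca, pc = 1, n_per_direction = 3)$positive
#> # A tibble: 3 x 2
#>   gene_id  loading
#>   <chr>      <dbl>
#> 1 gene0064   0.108
#> 2 gene1519   0.104
#> 3 gene0160   0.103
```

The simulation plants a two-group effect on 10% of the genes; PC1 absorbs
it (52.7% of the variance, against ~5% for the noise components), and the
highest-loading genes are the planted ones.  Annotating the components
against a GO mapping with a term planted on the up-regulated genes:

```r
go  <- simulate_go(sim$truth$genes$gene_id,
                   with(sim$truth$genes, gene_id[affected & lfc > 0]),
                   seed = 42)
enr <- pca2go_all(pca, go, pcs = 1:2)
head(dplyr::select(tibble::as_tibble(enr), pc, direction, term_id,
                   n_annotated_selected, expected, p_value, fdr), 3)
#> # A tibble: 3 x 7
#>      pc direction term_id    n_annotated_selected expected     p_value       fdr
#>   <int> <chr>     <chr>                     <int>    <dbl>       <dbl>     <dbl>
#> 1     1 positive  GO:0000001                   13    3.92  0.000000103   3.20e-6
#> 2     1 positive  GO:0000041                    3    0.963 0.0631        9.77e-1
#> 3     1 positive  GO:0000014                    1    0.275 0.246         1   e+0
```

The planted term (`GO:0000001`) tops the positive direction of PC1: all
13 genes of the loading quantile carry it where 3.9 were expected by
chance.  `autoplot(pca)`, `plot_scree(pca)`, `plot_sample_heatmap()` and
friends render the standard figures; `tidy()`/`glance()` methods expose
every result as a tibble.

For a file-based run, the CLI mirrors the library:

```sh
pcalens simulate --outdir sim --seed 3
pcalens run --counts sim/counts.tsv --metadata sim/metadata.tsv \
            --go sim/go.tsv --outdir out
pcalens report --state out/session.tar --out report.html
```

## Acceptance script

`scripts/acceptance.R` re-runs the complete pipeline from scratch on the
simulated stated world — generating the inputs, normalizing, fitting the
dispersion trend, transforming, running both PCA views and the component
annotation, archiving the session and rendering the report — and writes a
JSON summary:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope

The interactive presentation layer of exploratory PCA tools (widgets,
live zooming, embedded editors) is out of scope by design: the rectangle
selection, outlier-removal and report operations are the programmatic
equivalents.  Regularized-log transforms, gene-level dispersion
shrinkage, differential testing, GO-graph-aware enrichment and t-SNE/
sparse PCA are likewise not goals; see the methods vignette
(`vignettes/pcalens-methods.Rmd`) for the modelling details, parameter
defaults and known limitations.
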