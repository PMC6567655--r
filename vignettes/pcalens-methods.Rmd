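---
title: "pcalens: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pcalens: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcalens)
options(pcalens.verbose = FALSE)
```

pcalens makes the exploratory stage of an RNA-seq analysis — normalization,
variance stabilization, PCA of samples and genes, and functional reading of
the principal components — scriptable and reproducible.  This vignette is
the package's own account of the statistics it implements: the models and
their assumptions, the tunable parameters with their defaults and
rationale, what the synthetic-data generators do and do not emulate, the
numerical conventions, and the known limitations.

## The data model

A dataset is a genes × samples matrix of non-negative integer read counts
plus a samples × factors metadata table.  `bind_experiment()` validates the
pair: samples present in both inputs are kept, in count-matrix order
(counts are treated as the primary object), and one-sided samples are
dropped with a warning.  Gene identifiers are case-sensitive and never
normalized; annotation lookup is exact-match.  How mismatched sample sets
should be resolved is a genuine design choice — intersect-and-warn was
picked because silent reordering and hard failure both hide common,
recoverable input mistakes.

Counts must be integral.  A `strict = FALSE` escape hatch accepts values
within 1e-6 of an integer (rounding them), because several upstream
quantifiers emit fractional expected counts; the default stays strict so
that corrupted files fail loudly.

## Normalization: median of ratios

Sequencing depth differs between libraries, so raw counts are not
comparable across samples.  The size factor of sample $j$ is

$$ s_j = \operatorname{median}_{i \in U} \frac{k_{ij}}{\left(\prod_{v=1}^{m} k_{iv}\right)^{1/m}}, $$

the median across genes of the ratio of the sample's count to the gene's
geometric mean, over the set $U$ of genes with no zero count (geometric
mean positive).  The estimator assumes most genes are not differentially
expressed, so the median ratio tracks depth rather than biology; it is the
standard normalization of count-based differential-expression frameworks,
and the package's implementation agrees with the DESeq2 reference to
1e-10 in the test suite.  Degenerate cases: a single sample gets $s = 1$
with a warning; if no gene is all-positive the function stops and advises
filtering or a pseudocount rather than silently normalizing on nothing.

Exactly scaled replicate columns satisfy $s_j = c_j / \bar c_g$ (the
multiplier over its geometric mean) — this closed form is what the
acceptance suite checks on random matrices.

## Variance-reducing transformations

Count variance grows with the mean, which would let high-count genes
dominate any Euclidean computation (PCA, distances).  Two transforms are
provided:

* **Shifted log**: $\log_2(k_{ij}/s_j + c)$ with pseudocount $c > 0$.
  The pseudocount default is 1 — the source material for this design
  only calls for "small positive" values, so the conventional 1 (which
  maps zero counts to zero) is used and exposed as a parameter.
* **Variance-stabilizing transformation (VST)**, the closed form for a
  negative-binomial family whose dispersion follows the trend
  $\operatorname{disp}(\mu) = a_0 + a_1/\mu$: with $q = k_{ij}/s_j$,

  $$ \mathrm{vst}(q) = \log_2 \frac{1 + a_1 + 2 a_0 q + 2\sqrt{a_0 q (1 + a_1 + a_0 q)}}{4 a_0}. $$

  The map is strictly increasing, finite for $q \ge 0$, equals
  $\log_2((1+a_1)/(4a_0))$ at zero, and runs parallel to $\log_2 q$ for
  large counts, so shifted-log and VST values differ by a constant in the
  high-count regime (asserted to within 0.05 in the tests).

A regularized-log transform is deliberately **not** implemented: its
shrinkage estimator belongs to the differential-expression framework this
package deliberately does not depend on, and two transforms suffice to
exercise every downstream stage.

### Fitting the dispersion trend

The trend parameters are estimated from the data in three steps:

1. per-gene method-of-moments dispersion on normalized counts,
   $d_i = \max((\widehat{\operatorname{var}}_i - \hat\mu_i)/\hat\mu_i^2,\ 10^{-8})$;
2. ordinary least squares of $d_i$ on $(1, 1/\hat\mu_i)$ over genes with
   $\hat\mu_i > \texttt{min\_mean}$ (default 1 — genes with near-zero
   means have wildly unstable moment dispersions);
3. one round of outlier trimming (drop genes whose absolute residual
   exceeds twice the MAD of the residuals, with the conventional 1.4826
   consistency constant) and a refit.  $a_0$ is clamped to $\ge 10^{-8}$
   and $a_1$ to $\ge 0$.

This is a deliberately self-contained approximation to the gamma-family
GLM trend fits of dedicated differential-expression engines, and its
accuracy envelope matters.  Parameter-recovery simulations (negative
binomial, 2000 genes, 12 samples, trend $(a_0, a_1) = (0.1, 5)$) show
$a_0$ recovered within a few percent, but $a_1$ systematically attenuated
by roughly 15–30%.  Two causes, both intrinsic to the estimator at this
sample size: the $1/\hat\mu$ regressor is noisy (classical
errors-in-variables attenuation of the slope), and the handful of
low-mean, high-leverage genes that identify the slope are exactly where
the moment estimator of $d$ is biased low (about −16% at $\mu = 3$ with
12 samples).  No realistic mean distribution removes the effect.  The
attenuation is documented rather than patched because the fitting
procedure is part of the package's contract; in practice a ~25% error on
$a_1$ perturbs the VST's low-count bend slightly and is invisible in the
stabilized variances (the decile test below passes with a wide margin).
Users needing sharper trend estimates at small $n$ should use a GLM-based
fitter and pass the result in via the `dispersion_trend()` constructor.

Two related numerical notes.  Flooring $d_i$ at $10^{-8}$ means that for
Poisson data (true dispersion zero) the fitted intercept does not land
exactly on the clamp: the floor truncates the negative half of the noise
distribution, leaving a small positive intercept of order $10^{-5}$ to
$10^{-3}$ — negligible against any real overdispersion, and asserted as
such in the tests.  And when the planted differential-expression signal is
left in the fit (10% of genes at $|\log_2 \mathrm{FC}| = 2$), the group
effect inflates apparent dispersions and partially cancels the
attenuation; the recovery tests therefore use a null simulation, where
the dispersion model actually holds, rather than profiting from that
cancellation.

## PCA of samples and of genes

All PCA views operate on the `ntop` most-variable genes of the
transformed matrix (row variance, descending, ties broken by input order;
default `ntop = 500`, exposed because the original interactive tools
leave it as a user widget without a stated default).  Conventions:

* Gene-wise centering is always on.  Scaling (dividing by per-gene SD) is
  off by default because variance-stabilized data are already on a common
  scale; when enabled, zero-variance genes are dropped with a warning.
* Deterministic signs: every loading column is flipped so its
  largest-magnitude entry is positive, making outputs identical across
  SVD implementations.
* `variance_explained` is the normalized eigenvalue spectrum; it sums to
  one over all retained components, and scores times transposed loadings
  reconstructs the centered data (both asserted at 1e-8 against an
  independent eigendecomposition oracle).

**Samples view** (`pca_samples()`): observations are samples.  Outlier
exploration (`pca_remove_samples()`) recomputes both the variable-gene
ranking and the PCA on the reduced sample set — whether the ranking should
be recomputed after removal was an open choice; recomputation was chosen
because the post-removal view should be exactly what the user would have
obtained had the outlier never been present.

**Genes view** (`pca_genes()`): observations are the `ntop` genes with
rows centered across samples; variables are the samples.  The biplot
arrows are the sample loadings scaled by the square root of each
component's eigenvalue (the correlation-biplot convention; the displays
this reproduces show, but never define, their biplot mathematics, so the
convention is stated here).  Rectangle gene selection
(`select_genes_in_box()`) is closed on all boundaries and returns genes
ordered along the x component — the programmatic equivalent of zooming
into a plot region.

**Multifactor view** (`pca_multifactor()`): two experimental factors
enter one PCA through a stacked matrix with one row per (gene, factor-1
level) — labelled `gene::level` — and one column per (factor-2 level,
replicate).  The construction requires a balanced design and reduces
exactly to the genes view when factor 1 has a single level.  This matrix
layout is a documented reconstruction: the interactive tool this view
emulates never specifies its construction, so the stacked form was chosen
because it makes the interesting contrast visible as geometry — genes
responding only to factor 2 have their level-rows nearly coincident,
while interaction genes separate.  In the packaged 2×2 simulation (6
samples per cell) 98.5% of factor-2-only genes fall below the 10th
percentile of the interaction genes' row-pair distances in the displayed
PC1–2 plane; the test asserts ≥ 95% rather than all, since a few
low-expressed planted genes are noise-dominated, and measures distance in
the leading plane because across all components unstructured noise
swamps both groups equally.

## Overview statistics

Library sizes are column sums.  "Robustly detected" genes are defined as
count ≥ `min_count` in ≥ `min_samples` samples (defaults 5 and 1) — the
phrase is conventional but undefined in the interactive tools, so the
definition is explicit and both thresholds are exposed; the robust total
is non-increasing in both, which the property tests exercise.  Sample
distances are Euclidean over all genes of the transformed matrix, with a
display ordering from average-linkage hierarchical clustering (linkage
choice documented here because none is standard).  Correlation matrices
(Pearson default, Spearman optional) are computed on normalized counts;
zero-variance samples yield missing rows rather than errors.  Gene
summaries (`gene_finder()`) group samples by the cross-product of any
factors and report type-7 (linear interpolation) quartiles — stated
because boxplot conventions differ between tools.

## Functional annotation of components

For each component and direction, `select_loading_quantile()` takes the
`ceiling(top_fraction × ntop)` genes with the most extreme loadings of
that sign (genes of the wrong sign are excluded even when within the
count; default `top_fraction = 0.025` per direction, following the
promoter-analysis lineage of this approach).  `enrich_fisher()` then
tests every GO term whose in-universe size lies in
`[min_term_size, max_term_size]` (defaults 5, 500) with the one-sided
hypergeometric upper tail

$$ p = P(X \ge k), \quad X \sim \mathrm{Hypergeom}(N, K, n), $$

where $N$ is the annotated universe, $K$ the term's genes in it, $n$ the
selected genes in it and $k$ the overlap; Benjamini–Hochberg correction
across the tested terms.  The p-values are validated against exhaustive
enumeration of all $\binom{N}{n}$ draws for every configuration with
$N \le 12$, and the null calibration (random terms, random selections) is
checked to land near the nominal 5% level.

Design choices: the default universe is the `ntop` PCA genes intersected
with the annotated genes — enrichment conditional on the genes actually
driving the components — switchable to all annotated genes
(`universe = "annotated"`).  Note the universe restriction to annotated
genes means a term covering the entire annotation is uninformative
($p = 1$), and sparsely annotated datasets shrink $N$.  No GO-graph
decorrelation (parent–child or elim-style) is performed; annotation files
are taken as given, with no ancestry propagation.  Both the loading
cutoff and the universe were genuinely open parameters; they are exposed
with the defaults above.

## Synthetic data: the stated world

`simulate_counts()` draws
$k_{ij} \sim \mathrm{NB}(s_j\, \mu_i\, 2^{\beta_i x_j},\ a_0 + a_1/\mu_i)$
with log-normal gene means.  The defaults are the package's stated world:
2000 genes; two groups of 6 samples; 10% of genes affected at
$|\log_2 \mathrm{FC}| = 2$ with random sign; mean distribution
$\log\mu \sim \mathcal N(\log 150, 1)$ — robustly expressed genes with a
central 95% range of roughly 20–1100 counts, chosen because the toolkit
targets filtered expression matrices rather than whole-annotation count
dumps; dispersion trend $(0.1, 5)$, typical of bulk RNA-seq at moderate
depth; library multipliers 1.  Two-factor designs split the affected
genes evenly between factor-1, factor-2 and interaction effects.  A truth
record (affected genes, signed fold-changes, effect types, true library
multipliers) accompanies every simulation so tests never reach into
generator internals, and the generator restores the caller's RNG state.

What the generator does **not** emulate: zero-inflation and dropout of
raw single-cell data (preprocessing is assumed upstream), batch
structure, gene–gene correlation, length/GC biases, and outlier counts.
A green recovery test therefore establishes that the pipeline recovers
planted mean-shift structure under clean negative-binomial sampling — not
that it is robust to the full messiness of real libraries.

`simulate_go()` plants one term whose overlap with a designated gene set
is controlled exactly, among log-uniformly sized random terms, giving the
enrichment stage a signal with a known right answer.

## Reproducibility: session archive and report

`run_pipeline()` executes the whole analysis from file inputs and records
every parameter plus every derived table in a `session_state`.  Tables
are serialized as TSV with `%.17g` floating-point formatting, which
round-trips doubles bit-identically; missing values are written as the
literal `NA`.  `save_state()` packs them with a JSON manifest carrying
md5 digests into a single tar archive (R's internal tar implementation,
so no external archiver is needed); `load_state()` verifies every digest
and fails with the offending table's name on mismatch, and warns when an
archive was written by a newer major version.  `render_report()` builds a
self-contained HTML document from the stored tables only — never from
live objects — so a loaded archive renders identically to the original
session; figures are inlined SVG, and two renders of the same state are
byte-identical except for the single timestamp line.

## Known limitations

* The dispersion-trend slope $a_1$ is attenuated at small sample sizes
  (see above); the VST itself is insensitive to this at the scale of the
  stabilization it provides.
* Classic per-term Fisher testing ignores the GO graph, so correlated
  parent/child terms co-appear in enrichment tables.
* The multifactor view requires a balanced design; unbalanced designs
  error rather than silently reweighting.
* `pca_multifactor`'s stacked construction, the biplot arrow scaling and
  the "robustly detected" definition are documented reconstructions of
  conventions their interactive ancestors leave unstated.
* Reports embed tables capped at 100 displayed rows per section; the
  full tables live in the archive and the exported TSVs.
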