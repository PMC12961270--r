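---
title: "Module-first correlation analysis for holo-omics data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module-first correlation analysis for holo-omics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holocorr)
```

## The problem

Holo-omics studies profile matched host and microbiome samples — say, a host
transcriptome, a 16S amplicon table and a metatranscriptome from the same
animals — and ask which host and microbial features co-vary, because such
co-variation is the first observable trace of a host–microbiome interaction.
The statistical obstacle is dimensionality: thousands to millions of features
against tens of samples. Testing every host-feature x microbial-feature pair
drowns in multiple testing, and latent-factor integrations must estimate
thousands of loadings from dozens of samples, then still need post-hoc
decoding to say which genes a factor means.

`holocorr` takes the module-first route. Each omics layer is reduced
independently to a handful of co-varying feature *modules*; each module is
represented by its most intramodularly connected member (its *hub*); and only
the hub profiles are correlated — across layers, across the host–microbiome
boundary, and against sample metadata — with multiple-testing control. The
output units stay named features, so a significant cell in the final heatmap
reads directly as "this host gene module tracks that microbial module".

## Module detection

Within one layer with expression matrix \(X\) (samples x features), the
workflow is the weighted correlation network construction familiar from
co-expression analysis:

1. **Similarity.** \(r_{ij}\) = Pearson (default) or Spearman correlation
   between features \(i, j\).
2. **Soft-thresholded adjacency.** Unsigned (default):
   \(a_{ij} = |r_{ij}|^\beta\); signed:
   \(a_{ij} = ((1 + r_{ij})/2)^\beta\). The exponent \(\beta \ge 1\)
   suppresses weak edges while keeping the network weighted.
3. **Topological overlap.** With connectivity
   \(k_i = \sum_{u \ne i} a_{iu}\),
   \[\mathrm{TOM}_{ij} =
     \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
          {\min(k_i, k_j) + 1 - a_{ij}},\]
   which rewards shared neighborhoods and stabilizes the clustering.
4. **Clustering.** Average-linkage hierarchical clustering of
   \(D = 1 - \mathrm{TOM}\), cut at a fixed height (`cut_height`, a fraction
   of the maximum merge height). Branches with at least `min_module_size`
   features become modules, labelled `M1`, `M2`, ... by decreasing size;
   the rest is `unassigned`.
5. **Merging.** Each module is summarized by its *eigengene* — the first
   principal component of the column-standardized member submatrix, unit
   norm, sign-oriented to correlate positively with the mean standardized
   member profile. While the best-correlated module pair has eigengene
   correlation at least \(1 - \texttt{merge\_cut\_height}\), the pair is
   merged.
6. **Hubs.** Intramodular connectivity
   \(k^{\mathrm{in}}_i = \sum_{j \in \mathrm{module}(i),\, j \ne i} a_{ij}\);
   the hub of a module is its maximal-\(k^{\mathrm{in}}\) member. Hubs are
   extracted after merging, from the final modules. The layer's output is
   the samples x hubs table, re-consumable as an ordinary feature table.

### Choosing the soft threshold

`soft_threshold_scan()` evaluates a candidate grid (default 1..20): at each
\(\beta\) it bins \(\log_{10} k\) into at most 10 occupied bins and regresses
\(\log_{10} p(k)\) on the mean \(\log_{10} k\) per bin. The fit is reported
as \(R^2\) signed by the negated slope, so scale-free-like (decreasing)
degree distributions score positively. The chosen power is the smallest
candidate reaching `rsq_target` (default 0.8); if none does, the
best-fitting candidate is used with a warning.

A caveat worth stating plainly: data dominated by a few large, strong
modules — including this package's own simulator output — is *not*
scale-free, so the scan's fallback branch fires and the selected power is
essentially arbitrary. For such block-structured data we recommend fixing
`power` explicitly; 6 is the long-standing unsigned default in the
co-expression literature, and it is what the package's validation
simulations use.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `power` | `"auto"` | soft-threshold exponent \(\beta\); fix it (e.g. 6) for block-structured data |
| `rsq_target` | 0.8 | scale-free fit considered adequate in the scan |
| `cut_height` | 0.99 | static cut as a fraction of the maximum merge height |
| `min_module_size` | 20 | smallest branch kept as a module |
| `merge_cut_height` | 0.25 | merge modules with eigengene correlation ≥ 0.75 |
| `sign_mode` | unsigned | whether anti-correlated features may share a module |
| `max_features` | 20000 | single-block size guard |

The cutter is deliberately the *static* height cut, not the dynamic hybrid
algorithm: the static variant is fully specifiable, deterministic and
testable, and the cut is a pluggable stage. The cost is sensitivity on data
where module and background dissimilarities are not well separated; the
dynamic cutter handles those shapes better, and users who need it can cut
the returned tree themselves (`cut_dendrogram_to_modules` exposes the
`hclust` object).

Module detection refuses missing values rather than imputing: correlation
networks under missingness have no agreed semantics, and silent pairwise
deletion changes the meaning of the adjacency. Impute or filter first.

## Cross-layer correlation

`calculate_correlations(X, Y)` correlates every feature of `X` with every
feature of `Y` — in the intended use, two hub tables, or a hub table against
encoded metadata. Options mirror the conventions of base R:

- **method**: `pearson` (t test on \(t = r\sqrt{(n-2)/(1-r^2)}\)),
  `spearman` (same t approximation on mid-ranks, at every n), or `kendall`
  (tau-b; exact two-sided p from the inversion-count null distribution for
  n ≤ 8 without ties, tie-corrected normal approximation otherwise). Fixed,
  documented behavior was preferred over silent method switching.
- **use**: `all.obs` (missing data is an error), `complete.obs` (casewise
  deletion computed once over the union of both layers' features),
  `pairwise.complete.obs` (per-pair deletion; the default). Pairs with fewer
  than `min_pairs` (default 5) complete observations get missing r and p —
  three-point correlations are noise.
- **adjust**: `fdr` (Benjamini–Hochberg), `holm`, `bonferroni`, `none`. The
  family is all pairs of *one* X x Y call — pooling across layer pairs would
  make a module's significance depend on how many other layers happened to
  be loaded. Metadata correlations are their own family for the same reason.
- **annotation**: asterisk labels use 0.05 / 0.01 / 0.001 cutoffs applied to
  *adjusted* p-values — the conservative reading; both raw and adjusted
  matrices are always returned and written, so users preferring stars on raw
  p can re-annotate without recomputing.

Categorical metadata is encoded before correlation: binary variables become
one 0/1 indicator, k-level variables become k one-hot features named
`var=level`. Correlating a 0/1 indicator with a hub is a scaled two-group
mean comparison, which is exactly the exploratory question asked of such
variables.

## The integrated figure

The user designates one *central* layer. Its hubs are ordered by
average-linkage clustering of correlation distance (\(1 - r\) between hub
profiles) — correlation distance matches the co-variation semantics of the
whole workflow — and displayed as the central heatmap, row-standardized by
default (hub profiles on different dynamic ranges are unreadable raw).
Metadata correlation blocks attach on the left, one block per additional
omics layer on the right; every block is reordered to the central leaf order
and refuses to render on any id mismatch. Correlation blocks share a
diverging scale fixed to \([-1, 1]\); significance labels are drawn per
cell. Sample columns are grouped by the declared sample annotations when
given, otherwise clustered.

## The simulator

`simulate_bundle()` generates the structure the workflow assumes, and
nothing more. Each planted module has a standard-normal latent factor
\(f\) over samples; member feature \(j\) is
\(x_j = a f + \sqrt{1 - a^2}\,\varepsilon_j\) with loading
\(a \in (0, 1]\), so the expected within-module feature correlation is
\(a^2\) and a module's hub tracks \(f\) increasingly well as the module
grows. Cross-layer couplings draw the two factors jointly bivariate normal
with correlation \(\rho\) (the full factor correlation matrix is checked for
positive semidefiniteness and infeasible coupling graphs are refused), so
the expected hub–hub correlation of a coupled pair is \(a_a a_b \rho\).
Numeric metadata is \(b f + \sqrt{1-b^2}\,\varepsilon\); binary metadata is
\(\mathbb{1}(f > 0)\) with flip probability \((1-b)/2\). Knockouts are
missing completely at random. An optional compositional mode exponentiates
and closes rows to the simplex to exercise the centered log-ratio path.

Draws flow from one master seed through fixed sub-streams — factors first
(one joint draw, since couplings span layers), then each layer's feature
noise, then metadata, then missingness — so adding a layer leaves earlier
layers' feature noise untouched; the joint factor draw does change when
modules are added.

What the simulator does **not** emulate: count noise and overdispersion,
zero inflation, compositional closure of real amplicon data (beyond the
optional mode), phylogenetic correlation among taxa, batch effects, or
non-Gaussian tails. Passing recovery and power checks therefore show that
the machinery is correct under the model's own assumptions — they do not
certify performance on any particular real dataset, where preprocessing
choices dominate.

## Preprocessing

Only two preprocessing utilities are built in, because they are the two the
workflow itself needs on sparse compositional layers: prevalence filtering
(a feature must be non-missing and, by default, non-zero in at least a given
fraction of samples) and the centered log-ratio transform
(\(\mathrm{clr}(x)_i = \ln x_i - \overline{\ln x}\) per sample, with a
pseudocount defaulting to half the smallest non-zero value when zeros are
present). The pipeline applies the filter before the CLR — filtering after
would change every sample's geometric mean reference — though both stages
are independently callable in either order. Everything else (CSS, VST,
batch correction) is left to upstream best practice, and the tool starts
from plain feature tables.

Sample alignment takes the intersection of sample ids across all tables in
lexicographic order: no layer is privileged before the user names a central
one, and a stable order makes reruns byte-identical.

## Numerical and design choices

- Ties for the hub (equal \(k^{\mathrm{in}}\)) break to the
  lexicographically smallest feature id, with a message — determinism over
  cleverness.
- Eigengene sign follows the mean standardized member profile, removing the
  PC sign ambiguity.
- The single-block algorithm errors above `max_features` (default 20 000)
  rather than silently blocking; block decomposition is an optimization the
  package does not claim.
- A previous run's output directory is never silently overwritten: the
  manifest is detected and the run aborts unless `overwrite = TRUE`, which
  removes exactly the files the old manifest lists.
- The run manifest records inputs with MD5 checksums, all parameters, every
  file written, the seed and the package version.

## Validation problem sizes

The package validates itself on simulated bundles at the scale the method
targets: 40 samples, 4 planted modules of 40 features plus 40 background
features for recovery (20 seeds; adjusted Rand index against the planted
partition, hub placement, eigengene–factor correlation), and two 3-module
layers with one \(\rho = 0.8\) coupling for detection power (50 seeds, BH
level 0.05), with independent-layer nulls (20 x 20 hub-scale pairs, 50
replicates) for the realized false-positive fraction. These sizes are where
the method is meant to live — dozens of samples, modules of tens of
features — and keep the full validation suite fast enough to run on every
change.

## Known limitations

- The static cut underperforms the dynamic hybrid cutter on dendrograms
  without clean branch separation.
- Spearman p-values are always the t approximation; exact small-n Spearman
  tables are out of scope.
- Pairwise correlation only: no partial correlations and no
  compositionality-aware association (SparCC-style); on compositional
  layers, CLR first and interpret accordingly.
- One hub summarizes a module; a hub is a real, nameable feature (the point
  of the design) but necessarily a lossy summary of broad or heterogeneous
  modules.
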