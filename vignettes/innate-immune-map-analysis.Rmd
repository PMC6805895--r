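---
title: "Scoring innate-immune polarization maps against single-cell expression"
author: "innatemapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring innate-immune polarization maps against single-cell expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(innatemapr)
```

# The problem

Curated signalling-map resources for the innate immune system in cancer
organise knowledge hierarchically: two *zones* (anti-tumor and pro-tumor
polarization) contain *meta-modules* (biological processes), which contain
functional *modules*, which contain signalling *pathways*, which finally
contain genes. `innatemapr` implements the analytical machinery such a
resource needs once the curation is done:

1. a data model for entities, reactions, tags and the four-level hierarchy,
   with GMT gene-set interchange;
2. reaction confidence scores — a publication-based reference score and a
   PPI-proximity functional score, both on a 0–5 scale where 0 means
   undefined confidence;
3. ranking of single cells along a latent polarization axis with
   stability-selected independent component analysis (ICA), and splitting
   them into two groups;
4. module/pathway/zone activity scores per group with t-tests and standard
   significance codes;
5. per-gene survival z-score summaries per meta-module with a χ² enrichment
   test;
6. content comparison against other gene-set resources.

Everything is exercised end to end on synthetic data with planted ground
truth, so each stage's recovery behaviour is measurable.

# The map data model

Entities carry free-text tags `MODULE:<NAME>`, `PATHWAY:<NAME>` and
`MAP:<NAME>`; the name is the maximal run of non-whitespace after the colon
and matching is case-sensitive, which makes the grammar unambiguous and
reversible (`parse_tags()` / `format()`). The hierarchy partitions
*containers*, not genes: each pathway belongs to exactly one module, each
module to one meta-module, each meta-module to one zone, while a gene may
sit in many pathways. Container gene sets are unions of their children's,
computed bottom-up and validated at construction
(`build_hierarchy()` raises on double parents, dangling names and empty
pathways).

Gene sets are exchanged as GMT (one set per line: name, description, gene
symbols, tab-separated). On write, the description field carries the
ancestry path (`zone/meta_module/...`) and genes are sorted
lexicographically so diffs are reproducible; readers should not rely on the
description convention.

```{r}
h <- build_hierarchy(
  zones        = list("Anti-tumor" = "M1", "Pro-tumor" = "M2"),
  meta_modules = list(M1 = "mod1", M2 = "mod2"),
  modules      = list(mod1 = c("p1", "p2"), mod2 = "p3"),
  pathways     = list(p1 = c("TLR4", "MYD88"), p2 = c("MYD88", "IRF3"),
                      p3 = c("TGFB1", "SMAD3")))
h
hierarchy_genes(h, "zone", "Anti-tumor")
```

# Reaction confidence scores

The **reference score (REF)** reflects the number and the weight of
publications annotating a reaction. Weights default to 1.0 for experimental
innate-immunity-specific articles and 0.5 for reviews and experimental
articles from non-immune cells; the weighted sum is floored and capped at 5,
so five directly supporting experimental papers saturate the scale. The
weights and the aggregation are declared package conventions, overridable
via the `weights` argument — the published resources state the 0–5 scale and
the three article types but not the weighting itself.

The **functional proximity score (FUNC)** takes all protein participants of
a reaction (reactants, products, regulators — other entity classes are
excluded), computes the mean breadth-first shortest-path distance between
all unordered pairs in an external PPI network, and bins it: mean distance
≤ 1 → 5, ≤ 2 → 4, ≤ 3 → 3, ≤ 4 → 2, above → 1. Unit-distance bins are again
a declared convention (`breaks` argument). A lone participant, a protein
absent from the network or a disconnected pair make the average undefined,
which maps to 0 — undefined confidence — rather than to any penalized finite
distance. Shortest paths are delegated to `igraph`.

# The synthetic-data generator

The generator produces every input the pipeline consumes, with ground truth
for recovery tests. Its defaults define the study conditions used by the
tests and the acceptance script:

| parameter | default | meaning |
|---|---|---|
| zones | 2 ("Anti-tumor", "Pro-tumor") | polarization dichotomy |
| meta-modules / zone | 2 | biological processes |
| modules / meta-module | 3 | functional modules (12 total) |
| pathways / module | 3 | signalling pathways (36 total) |
| genes / pathway | 15 | 540 genes, unique per pathway |
| cells | 200 | single cells |
| latent | bimodal (±1 + N(0, 0.1²) jitter) | polarization gradient `t` |
| loading `a` | 1.0 | effect size of active genes |
| noise sd `σ` | 0.5 | log-scale Gaussian noise |
| active modules | 50% (3 per zone) | modules carrying the gradient |

Expression is generated directly on the log scale as
`x[g, c] = s_g · t_c + ε`, with `s_g = +a` for genes of active anti-tumor
modules, `−a` for active pro-tumor modules and 0 otherwise, and
`ε ~ N(0, σ²)`. The bimodal latent is the default because ICA requires a
non-Gaussian source and the cell groups of interest are the "extreme" cells
of one component; a uniform alternative is provided. The group label is the
sign of `t`. The 50% active fraction is split evenly across zones so both
polarization directions carry signal and component orientation is
well-defined.

What the generator deliberately does **not** emulate: scRNA-seq count noise
(dropout, library-size variation), batch effects, multiple latent
components, or correlated background genes. Passing recovery tests
therefore show that the pipeline's machinery is correct under its own
model assumptions, not that real tumor single-cell data would behave as
cleanly.

The PPI generator overlays dense within-pathway edges (p = 0.8) on an
Erdős–Rényi background (p = 0.01), giving FUNC something real to detect;
the survival generator draws `z ~ N(μ_m, 1)` per gene around a planted
meta-module mean with exact two-sided normal p values.

# Cell ranking by stability-selected ICA

Expression is log2-transformed if raw (`log2(x + 1)`) and every gene is
mean-centered across cells. The ICA stage then:

1. **whitens** the matrix by truncated SVD to `n_components`
   (default `min(10, cells − 1)`);
2. runs a **fixed-point ICA** with the log-cosh contrast (`g = tanh`) and
   symmetric decorrelation from a seeded random orthogonal start.
   Convergence is declared when the largest sign-invariant direction change
   falls below `tol = 1e-4` (at most `max_iter = 200` iterations). Weakly
   non-Gaussian directions drive the plain iteration into a period-2
   oscillation, so when the direction change stops halving the update takes
   a sign-aligned half-step — the classic stabilized fixed point. This
   leaves clean problems untouched (they converge in a couple of
   iterations) and makes near-Gaussian directions settle;
3. repeats 1–2 over `n_runs = 20` runs, each on a **bootstrap resample of
   the gene rows** (seeded per run). Resampling is what makes the stability
   index informative: with restarts alone, even pure-noise optima are
   perfectly reproducible, whereas a component that survives data
   perturbation is a property of the data, not of the optimizer;
4. **pools** all components and clusters them greedily by absolute Pearson
   correlation of their cell projections at threshold 0.85 (each cluster
   seeds on the unassigned component with most unassigned neighbours).
   A cluster's **stability index** is its mean within-cluster similarity
   (0 for singletons) minus its mean similarity to all other components,
   clamped to [0, 1]. The returned component per cluster is the member
   closest to the cluster centroid; components are sorted by stability and
   the top one is **IC1**.

A top stability below 0.5 — the "sufficiently stable" threshold — triggers
a warning, not an error: on pure Gaussian input that is the expected
outcome. Loadings of the returned components are per-gene least-squares
coefficients on the component's cell projection, so they are defined on the
original (un-resampled) genes.

Because an independent component's sign is arbitrary, IC1 is **oriented**
so that its mean loading over the anti-tumor zone's genes is non-negative
(an exactly zero mean leaves it unchanged; the operation is idempotent).
This is a convention introduced to make "group 1" reproducible.

Two grouping rules mirror the two use cases: `split_by_sign()` (group 1 =
positive IC1 projection, group 2 = negative, exact zeros unassigned) and
`split_by_quartiles()` (group 2 ≤ Q1, group 1 ≥ Q3 with linear-interpolation
quantiles, middle unassigned; heavy boundary ties pushing a group past 40%
of cells are an error). PCA coordinates for plotting come from the same
SVD, signs fixed so each component's largest-magnitude loading is positive.

```{r, fig.width = 5, fig.height = 4}
spec <- simulation_spec(seed = 3)
map <- generate_map(spec)
sim <- generate_cells(map$hierarchy, spec)
expr <- preprocess(sim$expression$values)
fit <- orient_component(run_ica(expr, seed = 3), map$hierarchy, expr)
fit
plot(fit, pch = 20, cex = 0.5)
```

# Module activity scores and group comparison

For each gene set, the genes at or above the median variability are
retained: per-gene sample variance (n − 1 denominator) is computed across
**all** cells — never per group, so both groups are scored on the identical
selection — and the top `ceiling(n/2)` genes are kept, ties broken
lexicographically. The module score of a cell is the mean of the selected
genes; a group's score is the mean over its cells (identical to averaging
the submatrix, pinned as per-cell-then-average).

Groups are compared with a two-sided Welch t-test on the per-cell scores
("standard t-test" is read as unequal-variance; the pooled-variance Student
variant is available via `var_equal = TRUE`). Significance codes follow the
standard mapping `***` < 0.001, `**` < 0.01, `*` < 0.05, `.` < 0.1. Zone
scores use the union of member-module gene sets with the same rule — one
rule at every level. Gene sets with no measured genes are flagged
`skipped`, never silently dropped.

`staining_table()` exports the red (upregulated) / green (downregulated)
coloring per set and group for map staining; ties are neutral.
`pathway_heatmap_matrix()` restricts to pathways with **more than**
`min_genes = 10` genes present in the expression matrix — measured genes,
not map molecules, since scoring can only use what was measured.

```{r}
groups <- split_by_sign(fit)
pol <- polarization_scores(expr, map$hierarchy, groups)
pol[, c("set", "mean_group1", "mean_group2", "t", "p", "code")]
```

# Survival z-score summaries

The survival stage takes a per-gene z-score table as input (z < 0 denotes
positive association with patient survival) — fitting the survival models
themselves is out of scope. `significant_genes()` keeps `p < alpha`
strictly. `map_overlap_enrichment()` compares the significant fraction
among map genes with a genome-wide background fraction via a 1-df Pearson
goodness-of-fit χ² (no continuity correction), calling enrichment at the
0.001 threshold; expected cells of zero are guarded out of the sum, and a
2×2 map-vs-genome contingency variant is available. The background fraction
is a required argument: whether a published background counts all genome
genes or all scored genes is a property of the external study, so the
package never hard-codes it.

`meta_module_summary()` reports, per meta-module, the mean z over **all**
scored member genes (not only the significant ones — the averaging
population behind published tables is unstated, and using all scored genes
makes the mean independent of the significance cut) plus counts of
significant genes split by sign. Genes in several meta-modules contribute
to each.

# Resource comparison

`overlap_fraction()` uses the map as denominator (the published overlap
percentages are shares of the map's content); the symmetric Jaccard index
is emitted alongside. `unique_genes()` is a set difference against the
union of the other resources. `module_unique_enrichment()` tests each
container for enrichment in map-unique genes with a hypergeometric upper
tail over the map universe and Benjamini–Hochberg adjustment — the test
behind "significantly enriched in unique genes" is a package convention.
Symbols are canonicalised by uppercasing and trimming whitespace only; no
alias resolution is attempted.

# Numerical choices and degenerate inputs

* Quantiles use R's default linear interpolation (type 7).
* Variance ties in gene selection break lexicographically; zero-variance
  comparisons with both groups constant raise rather than return NaN.
* `avg_pairwise_distance` treats "undefined" as a value (`NA`), not an
  error; FUNC maps it to 0.
* All generators are pure functions of their seed; `run_ica` derives
  per-run seeds as `seed + 0:(n_runs−1)` and accepts explicit `run_seeds`
  (passing identical seeds reproduces identical components, making the
  stability ceiling of 1 testable).
* The test-suite and acceptance problem sizes (200 cells, 540 genes, 10
  seeds, 500 null modules, 100 random graphs) were chosen so the full
  pipeline re-runs in well under a minute each while keeping Monte-Carlo
  tolerances meaningful.

# Known limitations

* The ICA model assumes one dominant non-Gaussian axis; data with several
  comparable sources will still return the most stable one, which need not
  be the biologically interesting one.
* The stability index is a heuristic cluster quality, not a probabilistic
  guarantee; its 0.5 threshold is a convention and only warns.
* Symbol matching is exact after canonicalisation; resources using
  different identifier namespaces must be mapped upstream.
* The synthetic generator's independence assumptions (no gene-gene
  correlation beyond the planted component) make recovery easier than on
  real single-cell data; treat recovery rates as upper bounds.
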