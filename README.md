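# innatemapr

Analytical machinery for hierarchical signalling-map resources describing
innate-immune polarization in the tumor microenvironment.

Curated map resources organise knowledge in four nested levels — two
polarization **zones** (anti-tumor, pro-tumor) → **meta-modules**
(biological processes) → functional **modules** → signalling **pathways**
with gene memberships — and annotate every entity with
`MODULE:`/`PATHWAY:`/`MAP:` tags and every reaction with two confidence
scores. `innatemapr` implements the analysis layer of such a resource for
systems-biology users who want to score it against data:

* **Map model** — validated four-level hierarchies, tag parsing, GMT
  gene-set read/write, entity/reaction records, per-module content tables.
* **Confidence scores** — the publication-based reference score REF and the
  PPI-shortest-path functional proximity score FUNC, both integers 0–5 with
  0 = undefined confidence.
* **Cell ranking** — FastICA (log-cosh contrast, symmetric decorrelation,
  SVD whitening) repeated over seeded bootstrap resamples; components are
  clustered across runs and the most *stable* one (IC1) ranks the cells
  along the latent polarization axis. Cells split into groups by projection
  sign or by extreme quartiles.
* **Module activity** — per gene set, the top-half most variant genes are
  averaged per cell (the module activity score); groups are compared with a
  two-sided Welch t-test and the standard significance codes
  (`***` p < 0.001, `**` < 0.01, `*` < 0.05, `.` < 0.1); staining and
  pathway-heatmap tables are exported for plotting.
* **Survival summaries** — overlap of map genes with a per-gene survival
  z-score table (z < 0 = positive association with survival), χ² enrichment
  of the significant fraction against a genome background, and mean-z /
  sign-count summaries per meta-module.
* **Resource comparison** — overlap fractions, map-unique genes,
  hypergeometric unique-gene enrichment with BH correction, literature
  recency statistics.
* **Synthetic data** — generators for every input (map, tagged entities,
  PPI graph, single-cell log expression with a planted bimodal polarization
  gradient, survival z-scores) with full ground truth, so every stage has
  measurable recovery behaviour.

## Worked example

Simulate the default study conditions (540 genes in a 2-zone map, 200
cells, bimodal latent gradient, noise sd 0.5), rank the cells and score the
map:

```r
library(innatemapr)

spec <- simulation_spec(seed = 3)
map  <- generate_map(spec)
sim  <- generate_cells(map$hierarchy, spec)

expr <- preprocess(sim$expression$values)          # center per gene
fit  <- orient_component(run_ica(expr, seed = 3), map$hierarchy, expr)
fit
#> <ica_result> 181 stability-selected components; IC1 stability 0.957

groups <- split_by_sign(fit)
groups
#> <cell_groups> 98 in group1, 102 in group2, 0 unassigned

abs(cor(fit$projections[, 1], sim$truth$latent, method = "spearman"))
#> 0.939
```

IC1 is the only component whose cluster of bootstrap runs is highly
reproducible (stability 0.957; everything else is far less stable), and its
per-cell projection tracks the planted gradient at Spearman ρ = 0.94. The
sign split recovers the planted groups exactly. Zone-level polarization
scores separate the groups:

```r
polarization_scores(expr, map$hierarchy, groups)[,
    c("set", "mean_group1", "mean_group2", "t", "p", "code")]
#>          set mean_group1 mean_group2    t         p code
#> 1 Anti-tumor        1.01      -0.971  131 2.99e-193  ***
#> 2  Pro-tumor       -1.01       0.970 -133 2.84e-192  ***
```

Group 1 (the anti-tumor side after orientation) scores high on the
anti-tumor zone and low on the pro-tumor zone; t is the Welch statistic on
per-cell module scores. Module-level scoring flags exactly the six planted
active modules at `***` and nothing else:

```r
tab <- score_all(expr, map$hierarchy, groups, level = "module")
subset(tab, code == "***")$set
#> "MM1_1_mod2" "MM1_2_mod1" "MM1_2_mod2" "MM2_1_mod2" "MM2_2_mod1" "MM2_2_mod3"
sim$truth$active_modules
#> "MM1_1_mod2" "MM1_2_mod1" "MM1_2_mod2" "MM2_1_mod2" "MM2_2_mod1" "MM2_2_mod3"
```

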