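# ecoplateNet

Desk-side analysis for soil-microbiome perturbation studies laid out as
treatments × replicates × sampling days — the design typical of herbicide
(or other agrochemical) soil experiments: a control and dosed treatments,
three replicate plots, and repeated sampling over weeks. The package
covers four analysis layers plus a fully seeded synthetic-data generator
that emulates such a study end to end, including planted ground truth for
benchmarking.

## What it computes

**Biolog EcoPlate profiling (community-level physiological profiles).**
From long-form OmniLog signal time series over the 31 EcoPlate carbon
sources: blank-corrected substrate activity `c_i = max(signal_i − blank, 0)`
at a chosen read time (default 96 h), AWCD = (1/31) Σ c_i, its time
course, six-guild substrate activity, and the functional diversity
indices

- Shannon–Wiener `H′ = −Σ p_i ln p_i`, with `p_i = c_i / Σ c`
- Simpson `D = 1 − Σ p_i²`
- McIntosh `U = √(Σ c_i²)`

**Community diversity.** Alpha diversity (Shannon; bias-corrected Chao1
`S_obs + F₁(F₁−1)/(2(F₂+1))` on integer counts), relative abundance and
top-k feature selection, Bray–Curtis dissimilarity, PCoA (classical
scaling) and PCA ordination.

**Co-occurrence networks.** Signed undirected networks from thresholded
Spearman correlations: genus–genus networks over the top 300 genera at
|ρ| > 0.9, p < 0.05, and taxa–gene networks over the top 30 phyla plus
the 12 C/N-cycle marker genes (mcrA, pmoA, cbbL, porA, accA, oorA; nirA,
nirK, nosZ, nxrA, nirS, nifH) at |ρ| > 0.6, p < 0.05. Topological
indices (nodes, edges, positive/negative edge percentages, diameter,
average path length, average degree 2E/N), hub detection by degree
quantile, and Gephi-importable GraphML / edge-list export.

**Group comparison.** Per-day one-way ANOVA across treatments with Tukey
HSD (or Fisher LSD) and compact letter displays (letters shared ⇔ not
significantly different), mean ± SE per cell — the standard
letters-over-bars annotation.

## Worked example

```r
library(ecoplateNet)

cfg   <- synth_config(seed = 1)          # 3 treatments x 3 reps x 7 days
study <- generate_synthetic_study(cfg)
nrow(study$design)
#> [1] 63

# EcoPlate metabolic activity at the 96-h plateau
prof <- blank_correct(study$plates, time_h = 96)
round(mean(awcd(prof)[study$design$treatment == "CK"]), 1)
#> [1] 138.7
round(mean(awcd(prof)[study$design$treatment == "T5"]), 1)
#> [1] 102.8          # high-dose treatment suppresses color development

# genus-genus co-occurrence network at |rho| > 0.9, p < 0.05
net <- build_network(study$genus, network_spec("taxa"))
topology(net)
#>   n_nodes n_edges pos_ratio_pct neg_ratio_pct diameter avg_path_length avg_degree
#> 1      15      30           100             0        1               1          4
```

The 15 nodes / 30 edges are exactly the three planted 5-genus correlated
blocks (each block is a complete K5: 10 edges), i.e. the network step
recovers the generator's ground truth with precision and recall 1 at
these settings.

A full run writing every stage's tables (AWCD curves, indices, alpha
diversity, ordinations, per-treatment networks + topology, letter
displays):

```r
run_pipeline(list(seed = 1), out_dir = "results/run1")
```

or from a shell: `Rscript inst/scripts/ecoplate-netcycle.R run --out results/run1`.

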