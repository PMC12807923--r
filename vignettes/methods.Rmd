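---
title: "Methods: EcoPlate profiling, diversity and co-occurrence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EcoPlate profiling, diversity and co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ecoplateNet analyzes soil-microbiome perturbation experiments with a
treatments × replicates × days layout. This vignette is the package's
account of the statistics it implements, the choices made where the
methodology is genuinely open, and what the synthetic benchmark does and
does not demonstrate.

## EcoPlate profiling

A Biolog EcoPlate reports color development (OmniLog units) for 31
carbon sources plus water blanks. The package reduces a plate to a
substrate-activity vector at a single read time (default 96 h, where
logistic color curves have plateaued) by blank subtraction with clipping:
`c_i = max(signal_i − blank, 0)`. Clipping is the dominant convention in
EcoPlate work and guarantees the nonnegative well proportions the
diversity indices require. Whether published EcoPlate indices are
computed on raw or blank-corrected signals is often unstated; both paths
are available here (corrected is the default — pass the uncorrected read
time series through the same functions to get the other reading).

Indices, with `p_i = c_i / Σc`:

* AWCD `= (1/31) Σ c_i` — overall metabolic activity;
* Shannon–Wiener `H′ = −Σ p_i ln p_i` over positive wells. The natural
  logarithm is used (the literature rarely states a base); it is a
  monotone rescaling only, so group comparisons are unaffected;
* Simpson `D = 1 − Σ p_i²` by default. The inverse form `1/Σ p_i²` is an
  option, not the default, because the complement form is bounded in
  [0, 1 − 1/31] and is the more common plate-profiling summary;
* McIntosh `U = √(Σ c_i²)`, the unnormalized index — not McIntosh
  evenness — since the raw Euclidean norm is what plate studies report
  as "U".

An all-zero plate leaves `H′` and `D` undefined; they are reported as
missing (with `U = 0`) rather than forced to 0, so degenerate plates are
visible downstream.

## Community diversity

Shannon diversity is computed on counts when the table is integer,
otherwise on relative abundances (the output records which). Chao1 uses
the bias-corrected estimator `S_obs + F₁(F₁−1)/(2(F₂+1))`, which is
defined when doubletons are absent; the classical `F₁²/(2F₂)` form is an
option. Chao1 is refused on non-integer tables: singleton and doubleton
counts do not exist for relative abundances, and silently rounding would
fabricate them.

Bray–Curtis dissimilarity is computed between sample columns. It is not
invariant to rescaling one sample's total, so tables with arbitrary
totals should be closed to relative abundances first; the package tests
document both behaviors.

Two ordinations are first-class: PCoA (classical scaling of any
dissimilarity, used with Bray–Curtis) and PCA on Euclidean distances.
Both appear in practice and they coincide on Euclidean input, which the
tests exploit as an equivalence oracle. Negative PCoA eigenvalues
(non-Euclidean input) are dropped and their total magnitude recorded as
`lost_inertia` — the simplest defensible policy; no Cailliez correction
is applied, so percent-explained values are relative to positive inertia
only.

## Co-occurrence networks

Networks are built from pairwise Spearman correlations among candidate
features: the `top_k` features by mean relative abundance over the
selected samples (300 genera in taxa mode; 30 phyla plus the 12
C/N-cycle marker genes in taxa–gene mode). An edge is kept when
`|ρ|` exceeds the threshold (0.9 taxa, 0.6 taxa–gene) *and* p < 0.05;
isolated nodes are removed. Thresholding uses the magnitude |ρ| rather
than signed ρ because reported networks of this kind include negative
edges; a signed-threshold option exists for the strict reading.

Design choices that matter:

* **Sample pooling.** By default all supplied samples enter one
  correlation; a treatment selector restricts to one treatment's samples
  across all days and replicates (n = 21 in the emulated design). Pooling
  across days means edges can reflect shared time trends as well as
  ecological association — unavoidable with this family of methods.
* **Significance.** p-values come from the two-sided t approximation
  `t = ρ√((n−2)/(1−ρ²))` on n−2 df, vectorized over the matrix. For
  small n a seeded permutation option is available; for tie-free data
  the Spearman null is distribution-free, so one permutation null (10⁴
  draws by default) is shared across all pairs, making the option exact
  up to Monte-Carlo error. With ties it is approximate.
* **Multiple testing.** No correction by default — raw p < 0.05 is the
  convention in this literature — but any `p.adjust` method can be
  switched on. At 300 candidates and |ρ| > 0.9 the rho threshold, not
  the p threshold, is binding anyway.
* **Zero-variance features** get ρ = 0, p = 1 against everything, so
  they can never enter a network.

Topological indices follow the usual reporting: node/edge counts,
positive/negative edge percentages, average degree 2E/N, diameter (the
longest geodesic within the largest connected component) and average
path length (mean geodesic over all connected pairs, unit edge lengths).
Pairs in different components are excluded from the average rather than
assigned infinite length — the same convention Gephi uses, which keeps
the numbers comparable with published tables. Hubs are nodes at or above
a degree quantile (default 0.95), ties included; "hub" has no standard
formal definition, so the quantile is exposed.

## Group comparison

For each response and sampling day, one-way ANOVA across treatments on
the replicate values, followed by Tukey HSD (SPSS's usual family-wise
default; Fisher LSD is available since published letter displays rarely
name the post-hoc) and a compact letter display via insert-and-absorb.
The display invariant — two groups share a letter iff their pairwise
test is not significant — is asserted programmatically on every output.
Letters start at "a" for the highest-mean group. Cell summaries are
mean ± SE with SE = sd/√n. No normality or homogeneity pre-tests are
run; with n = 3 per cell they would be uninformative, and this matches
field practice. Days are treated independently (no repeated-measures
structure), which inflates the family of tests across days — a known
limitation of the per-day-letters presentation itself.

## The synthetic-data generator

The generator emulates the study conditions the package targets: 3
treatments (CK/T1/T5 at 0/180/900 g a.i. ha⁻¹) × 3 replicates × 7 days
(0, 1, 5, 10, 20, 30, 60) = 63 samples.

**Taxa.** 300 genera with power-law rank abundance, base log-abundance
`μ_g = −s·ln(rank)` with exponent s = 1. Each sample draws a latent
Gaussian vector `z` with block-diagonal correlation — a Gaussian copula;
Spearman correlation is invariant to the exponentiation, so planted rank
correlation survives into the abundance scale — and the abundance is
`exp(μ_g + σ·z_g)` with a single latent scale σ_taxa = 0.5. That one
scale both disperses replicates and carries the planted correlation:
setting it to zero yields identical columns, which makes the noise-free
degenerate case exactly reproducible. Defaults plant three 5-genus
blocks at copula ρ = 0.95 (mid-abundance ranks 11–25) and one abundant
responder genus with a 10-fold increase in T5 on post-application days;
day-0 samples are pre-treatment and never receive responder effects.
Columns are closed to relative abundances. The phylum table aggregates a
fixed genus→phylum map (30 phyla, 8 dominant via a weighted round-robin
assignment).

**Genes.** The 12 C/N marker genes and 6 CAZy aggregates are noisy
linear combinations of genus abundances through a known loading matrix
(default: each gene loads 1.0 on a distinct abundant genus + 0.3 on a
secondary one) times multiplicative lognormal noise σ_gene = 0.2, which
keeps abundances nonnegative and rank correlations strong.

**Plates.** Logistic color development
`K_sub · m_treat / (1 + e^{−r(t−t₀)})` with r = 0.1 h⁻¹, t₀ = 36 h and
truncated Gaussian read noise (σ = 4 OmniLog units) on a 0/24/48/72/96 h
grid; substrate asymptotes K are high for the empirically fast EcoPlate
substrates, low for the slow ones, and zero for the two substrates soil
communities typically cannot metabolize (2-Hydroxy Benzoic Acid,
α-Ketobutyric Acid). Treatment multipliers (CK 1.0, T1 0.9, T5 0.75)
encode activity suppression growing with dose.

Determinism: every artifact draws from its own substream seeded from
(master seed, artifact name), so adding an output never perturbs the
others, and identical configurations are bit-identical.

**What the benchmark shows — and does not.** Recovery of planted blocks
at |ρ| > 0.9 with 63 samples demonstrates that the thresholding,
candidate selection and p-value machinery are correct, not that the
thresholds are well-calibrated for real soil communities: real
communities have diffuse correlation structure, compositional coupling
far stronger than three small blocks induce, uneven sequencing depth,
and taxa–environment confounding, none of which the generator emulates.
Effect sizes (fold changes, block correlations, activity multipliers)
are conventional placeholders, not biological estimates.

## Problem sizes and numerics

The test suite exercises the full 63-sample design where the check is
about study structure (planted-block recovery, responder letters, design
constants) and scales down elsewhere: graph-metric oracle comparisons
run on 100 random graphs of ≤ 30 nodes against Floyd–Warshall; the
permutation-vs-t comparison uses n = 21 over 50 trials; ANOVA
calibration uses 2,000 null simulations (rate required within
0.05 ± 0.02). Numeric tolerances: closed-form index checks at 1e-9 or
tighter; Spearman closed-form agreement at 1e-12; edge-list exports
write ρ and p at 6 decimals and round-trip exactly at that precision.

One published-style consistency check deserves a note: average degree
must equal 2E/N exactly, and the package asserts this on reported
(N, E) pairs; tables in the literature occasionally contain rows where
the printed average degree is inconsistent with the printed counts, and
such rows are excluded from the check rather than reproduced.

## Known limitations

* Correlation networks on compositional data are biased (negative
  correlation induced by closure); SparCC/SPIEC-EASI-style corrections
  are out of scope, as is community detection/modularity.
* No rarefaction, UniFrac or PERMANOVA; no phylogeny is consumed.
* The Tukey/LSD machinery assumes independent errors within a day;
  repeated-measures dependence across days is not modeled.
* The permutation p-value option treats tied data approximately.
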