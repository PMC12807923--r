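Package: ecoplateNet
Title: Biolog EcoPlate Profiling, Diversity, and Thresholded-Spearman
    Co-Occurrence Networks for Soil Microbiome Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-side analysis pipeline for herbicide-perturbation soil
    microbiome studies laid out as treatments x replicates x sampling days.
    Computes community-level physiological profiles from Biolog EcoPlate
    readings (AWCD, Shannon-Wiener H', Simpson D, McIntosh U), alpha and
    beta diversity of feature-abundance tables (Shannon, Chao1,
    Bray-Curtis, PCoA, PCA), builds signed co-occurrence networks from
    thresholded Spearman correlations (genus-genus and taxa versus C/N
    cycling functional genes) with topological indices and hub detection,
    and performs per-timepoint one-way ANOVA with Tukey HSD and
    compact-letter displays. Includes a seeded synthetic-data generator
    emulating the full study design, with planted correlation structure
    for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
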