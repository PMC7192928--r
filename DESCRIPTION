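Package: endemscale
Title: Scale Dependence of Weighted and Phylogenetic Endemism
Version: 0.1.0
Authors@R: person("Avery", "Quinn", email = "avery.quinn@example.org",
    role = c("aut", "cre"))
Description: Tools to study how endemism metrics respond to spatial grain,
    spatial extent and taxonomic lumping depth. Computes range-weighted
    endemism and phylogenetic endemism on gridded presence-absence data,
    slices ultrametric phylogenies at time depths to emulate taxonomic
    lumping, detects percentile hotspots, scores their coverage by
    protected areas, and fits linear mixed models of endemism against
    environmental heterogeneity with a spatial autocovariate. Includes a
    synthetic-data generator (Yule posterior tree sets, spreading-dye
    ranges, spatially autocorrelated environmental layers, nested region
    partitions, patchy protection layers) so the full pipeline runs
    end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
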