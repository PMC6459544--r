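Package: ionopattern
Title: Spatial Pattern Statistics and Synthetic Cohorts for Zebrafish
    Epidermal Ionocyte Patterning
Version: 0.1.0
Authors@R:
    person("Pattern", "Maintainers", email = "maintainers@ionopattern.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of epidermal cell point patterns on the
    ventral surface of zebrafish embryos at the end of gastrulation.
    Computes compartmentalized cell counts (p63+ stem cells, dlc-p63+
    keratinocyte progenitors, dlc+p63+ ionocyte progenitors and the rare
    dlc+p63- mislabel class, each with BrdU+ subsets), cell densities,
    proliferation fractions, normalized nearest-neighbour spacing in
    cell-diameter units, the angular width of the ionocyte domain at the
    embryo centroid, connected-pair and cluster decompositions of dlc+
    cells, a closed-form monolayer diameter-to-cell-number predictor, and
    Welch two-sample comparisons with mean +/- s.e.m. summaries. A
    seed-reproducible synthetic-embryo generator emulates the statistical
    structure of the imaging data (dart-thrown epithelial packing,
    sequential lateral-inhibition selection of progenitors, chained
    co-selection producing contiguous clusters, per-compartment BrdU
    labelling) so that every stage of the pipeline is testable without
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
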