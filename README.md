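# ionopattern

Spatial pattern statistics and synthetic cohorts for epidermal ionocyte
patterning in zebrafish embryos.

## The problem

At the end of gastrulation the ventral surface of a zebrafish embryo is a
monolayer of p63+ epidermal stem cells from which Delta–Notch lateral
inhibition (*dlc*) selects scattered dlc+ ionocyte progenitors; the
remainder become keratinocyte progenitors. Studies of this system quantify,
per embryo, compartment counts (p63+, dlc−p63+, dlc+p63+, the rare
dlc+p63− mislabel class, each with a BrdU+ subset), densities in
cells·µm⁻², the mean dlc+ cell diameter, the normalized nearest-neighbour
spacing of dlc+ cells in the central area, the angular width of the dlc+
domain at the embryo centroid, connected pairs and clusters of dlc+ cells,
and Welch *t* contrasts between conditions.

`ionopattern` is a reusable, tested implementation of that analysis for
anyone working with annotated cell coordinates from such images — plus a
seed-reproducible synthetic-embryo generator that emulates the statistical
structure of the data, so every stage of the pipeline is testable without
any microscopy download.

## The statistics at its core

For dlc+ cells at positions $x_i$ with mean recorded diameter $\bar d$:

* **Normalized nearest spacing** (central area, 40% of the embryo
  diameter): $s_i = \min_{j \ne i} \lVert x_i - x_j \rVert / \bar d$,
  averaged per embryo. A hard-core lateral-inhibition pattern concentrates
  $s_i$ just above the inhibition radius (reported range 1.29–1.54).
* **Connected pairs / clusters**: edges between cells with
  $\lVert x_i - x_j\rVert < 1.25\,\bar d$ (strict); clusters are connected
  components, an isolated cell counting as size 1.
* **Domain angle**: width of the smallest arc, seen from the embryo
  centroid, containing all dlc+ cells — proportional to the area of the
  wedge-shaped ionocyte domain.
* **Monolayer predictor**: a fractional diameter change $\delta$ predicts a
  cell-number change per unit area of $100\,[(1+\delta)^{-2}-1]$ %.
* **Group contrasts**: per-embryo statistics first, then mean ± s.e.m.,
  percent change of means, and Welch's *t* with Welch–Satterthwaite df,
  two-tailed.

## Worked example

```r
library(ionopattern)
cfg <- cohort_config(presets = default_presets()[c("wild_type", "hom")],
                     n_embryos_per_condition = 8, seed = 42)
cohort <- generate_cohort(cfg)
s <- summarize_cohort(cohort$cells, cohort$geometry)
head(s[, c("embryo_id", "n_p63", "n_iono", "mean_norm_spacing",
           "domain_angle_deg", "max_cluster")], 4)
#>      embryo_id n_p63 n_iono mean_norm_spacing domain_angle_deg max_cluster
#>  wild_type_001  1270     57          1.442155         61.94374           1
#>  wild_type_002  1221     57          1.491546         61.89201           1
#>  wild_type_003  1186     57          1.488928         62.42280           1
#>  wild_type_004  1280     55          1.423029         60.55911           1
```

Each row is one embryo: ~1,222 p63+ stem cells, ~57 dlc+ progenitors
spaced ~1.45 progenitor diameters apart in a ~62° ventral domain, and no
clusters (the wild-type hard core at 1.3 diameters exceeds the 1.25
contact threshold).

```r
compare_conditions(s, "wild_type", "hom",
                   statistics = c("n_p63", "n_iono", "pct_brdu_kerat"))
#>       statistic percent_change         t       df            p tier
#>           n_p63      -22.99087 -12.96386 13.60935 4.824166e-09  ***
#>          n_iono      -29.11111 -23.86048 12.64750 6.772373e-12  ***
#>  pct_brdu_kerat      -26.23891 -39.64150 13.44691 2.537191e-15  ***
```

The homozygous-mutant preset loses ~23% of its stem cells and ~29% of its
ionocyte progenitors relative to wild type, with highly significant Welch
tests — the same contrast structure the published figures report.

`reproduce_reported_changes()` recomputes every printed percent-change
claim from the printed group means; five claims reproduce exactly to one
decimal, and the three known printed rounding inconsistencies are flagged
as such (see the methods vignette).

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/ionopattern", package = "ionopattern"))')
Rscript $CLI run --out demo --seed 7       # simulate + analyze + compare
Rscript $CLI simulate --config cfg.json --out demo
Rscript $CLI analyze --cells demo/cells.csv --geometry demo/geometry.csv --out demo/summary.csv
Rscript $CLI compare --summary demo/summary.csv --reference wild_type \
        --tests het,hom --out demo/comparisons.csv
Rscript $CLI reproduce                     # printed-claim reproduction table
```

Artifacts are plain CSV (`cells.csv`, `geometry.csv`, `summary.csv`,
`comparisons.csv`) plus a deterministic `manifest.json`; identical
configuration and seed give byte-identical outputs.

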