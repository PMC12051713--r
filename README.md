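# clonedisp

Quantify how strongly fluorescently barcoded clonal subpopulations of a
tumor (or any labeled cell mixture) intermingle in space. When cells
carrying stable color barcodes — canonically six classes: red, green,
blue, orange, purple, cyan — expand from single founders, they either
form demarcated colonies or disperse through each other. `clonedisp`
turns nucleus-detection exports and multi-label section images into a
single, comparable **Dispersal Score**, validates it on a clonal-growth
simulator with a known mixing dial, and carries the phenotype through to
a gene signature and survival stratification.

## The statistic

For cell $x_i$ of population $P_k$, let
$d(x_i, P_k) = \min_{l \neq k} d(x_i, x_{j \in P_l})$ — the distance to
its nearest neighbor from a *different* population. The score is

$$D = \left( \frac{1}{N} \sum_{k=1}^{N} \frac{1}{n_k}
      \sum_{i=1}^{n_k} d(x_i, P_k) \right)^{-1}$$

over the $N$ populations: the inverse of the unweighted across-population
mean of the per-population mean minimum cross-population distance. High
$D$ = intermingled, low $D$ = segregated. The metric $d$ comes in three
flavors — cell-level Euclidean (1/length), cell-level nearest-neighbor
*order* (the rank of the first foreign cell in the distance-sorted
neighbor list; dimensionless, $D \in (0,1]$), and pixel-level Euclidean
for section scans, computed with an exact Euclidean distance transform.

## Worked example

Simulate compact versus fully mixed clonal growth on a 64×64 lattice
(six populations, 30 founders, growth stopped at 75% occupancy) and
score both — same seed, mixing probability 0 vs 1:

```r
library(clonedisp)
seg <- simulate_clonal_growth(growth_config(mixing_probability = 0, seed = 11))
mix <- simulate_clonal_growth(growth_config(mixing_probability = 1, seed = 11))
score_celltable(seg$cells, "neighbor_order_cell", id = "q0")
#> <dispersal_result> metric=neighbor_order_cell  D=0.0209816  [dimensionless (1/rank)]
#>   N=6 populations; per-population mean d:
#>    blue    cyan   green  orange  purple     red
#> 65.1675 11.7417 28.2281 50.0803 86.8915 43.8552
score_celltable(mix$cells, "neighbor_order_cell", id = "q1")
#> <dispersal_result> metric=neighbor_order_cell  D=0.833913  [dimensionless (1/rank)]
#>   N=6 populations; per-population mean d:
#>   blue   cyan  green orange purple    red
#> 1.2877 1.2863 1.1111 1.2171 1.1115 1.1813
```

In the segregated run a cell must look past ~44 same-color neighbors on
average before meeting another population ($D \approx 0.02$); in the
mixed run the first or second neighbor is already foreign
($D \approx 0.83$). The pixel-level metric on the mixed run's raster
tells the same story in distance units — nearly every labeled pixel
touches a foreign pixel:

```r
pixel_dispersal_score(mix$image)
#> <dispersal_result> metric=euclidean_pixel  D=0.991028  [1/length]
#>   N=6 populations; per-population mean d:
#>   blue   cyan  green orange purple    red
#> 1.0145 1.0159 1.0041 1.0106 1.0068 1.0024
```

Downstream, `correlate_genes_with_dispersal()` →
`select_positive_significant()` → `intersect_signatures()` derive a
dispersal gene signature from two screening contexts,
`signature_zscore()` + `stratify_by_score()` split samples into
high/low signature groups, and `km_logrank()` compares their survival.
`tumor_volume()` (the 0.5·l·w·h caliper formula) and
`max_growth_rate()` (max sliding-window log-slope) cover the growth-rate
bookkeeping. A thin command-line front end with `score`, `simulate` and
`signature` subcommands ships in `inst/cli/clonedisp.R`.

See the vignette (`vignettes/dispersal-scores.Rmd`) for the model,
parameter choices, and what the synthetic validation does and does not
demonstrate.

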