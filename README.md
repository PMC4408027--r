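# twigwood

Quantitative wood anatomy for twig cross-sections, and the statistics
that go with it.

Angiosperm twig wood is a mosaic of tissues — fibres (wall + lumen),
axial and ray parenchyma, vessels (wall + lumen), very small conduits
(maximum lumen diameter < 15 µm), and occasionally mucilage canals. The
division of cross-sectional area among these tissues varies several-fold
between species even at similar bulk wood density, and it correlates with
ecological traits such as plant height, leaf area per sapwood area, and
twig stiffness. twigwood implements the full measurement-and-analysis
chain used in comparative studies of this kind:

* **Stereology** — tissue area fractions from a labeled section by
  systematic point counting: fraction = point hits / total points, with
  binomial standard errors and the 300-point minimum rule
  (`overlay_grid()`, `count_points()`, `fractions_from_counts()`).
* **Vessel morphometrics** — connected-component extraction of vessel
  lumens, the strict 15-µm small-conduit partition, and the population
  statistics
  `A` (mean lumen area, mm²), `N = VLF / A` (mm⁻²), `S = A / N` (mm⁴),
  and the hydraulically weighted diameter `D_H = Σd⁵ / Σd⁴`
  (`extract_vessels()`, `partition_conduits15()`, `vessel_stats()`).
* **Derived traits** — Archimedes wood density, ellipse pith/sapwood
  areas, SLA and leaf-area-to-sapwood-area ratio, three-point-bending
  modulus of elasticity with the 20:1 span rule, composite fractions
  (total parenchyma/fibre/vessel, wall), species means, and trait
  summaries with the zero-exclusion n-fold rule.
* **Statistics** — pairwise trait correlation matrices where the test is
  gated by Shapiro–Wilk normality: Pearson's *r* when both traits screen
  normal, Spearman's ρ otherwise; significance bands at 0.05/0.01/0.001;
  no multiple-testing correction (`correlation_matrix()`).
* **Synthetic data** — labeled wood mosaics with pixel-exact ground-truth
  fractions (`generate_section()`), and 69-species × 3-replicate trait
  tables built from a Gaussian copula with published-style marginal
  ranges and correlation structure (`generate_trait_table()`), so every
  stage can be validated against known truth.

See `vignettes/twigwood-methods.Rmd` for the model and design notes.

## Worked example

Generate a labeled section, measure it, and run the species-level
analysis:

```r
library(twigwood)

sec <- generate_section(section_spec(image_size_px = c(600, 600),
                                     rng_seed = 1))
sec
#> <labeled_section> 600 x 600 px at 1 um/px (0.36 mm^2 in sector)
#>   VESSEL_LUMEN     0.1305
#>   VESSEL_WALL      0.0400
#>   AXIAL_PARENCHYMA 0.1400
#>   RAY_PARENCHYMA   0.2100
#>   FIBRE_LUMEN      0.1305
#>   FIBRE_WALL       0.3211
#>   CONDUIT15        0.0200
#>   MUCILAGE_CANAL   0.0078

est <- estimate_fractions(sec, spacing_px = 25)   # 576 grid points
measure_vessels(sec, fractions = est)
#>         A     N          S     Dh   VLF n_vessels n_conduits15
#> 1 0.00104  120. 0.00000872 0.0391 0.125        45           99
```

The mean vessel lumen is 0.00104 mm², there are ~120 vessels per mm²
(their lumens summing to the grid-estimated fraction 0.125 of the
section), and the hydraulically weighted diameter is 0.039 mm — a large
conduit counts far more than its share of the mean because hydraulic
conductance scales with the fourth power of diameter.

```r
tab <- generate_trait_table(trait_table_spec(rng_seed = 1))  # 69 x 3
sm  <- species_means(tab)
summarize_traits(sm)[c(3, 6, 12), c("trait", "low", "high", "average", "nfold")]
#>   trait   low  high average nfold
#> 1 TPF   0.135 0.617   0.355   4.6
#> 2 TFF   0.198 0.741   0.453   3.7
#> 3 WF    0.160 0.615   0.362   3.9

corr <- correlation_matrix(sm, traits = setdiff(trait_columns(), "MCF"))
correlation_of(corr, "TFF", "TPF")
#>   method  estimate        p     n
#> 1 pearson   -0.874 1.14e-22    69
correlation_of(corr, "WF", "MOE")
#>   method   estimate           p     n
#> 1 spearman    0.558 0.000000635    69
```

Total fibre and total parenchyma fractions are strongly inversely
correlated (*r* ≈ −0.87 here): across species, fibres and parenchyma
trade off against each other for cross-sectional area, roughly
orthogonally to wood density. The wall fraction correlates positively
with twig stiffness (Spearman, because MOE is right-skewed).

`run_pipeline(pipeline_config(out_dir = "out"))` chains the stages —
simulate, measure, derive, aggregate, correlate, summarize — and writes
CSVs plus a stacked tissue-fraction bar chart and trait scatter plots.
Real data enter through `read_label_map()` (indexed PNG + JSON palette
sidecar) and `read_trait_dataset()` (CSV/XLSX with an explicit column
mapping).

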