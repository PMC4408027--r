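---
title: "Quantifying twig wood anatomy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying twig wood anatomy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twigwood)
```

## The problem

Angiosperm twig wood is a mosaic of tissues — fibres (wall and lumen),
axial and ray parenchyma, vessels (wall and lumen), very small conduits,
and occasionally mucilage canals. How the cross-sectional area is divided
among these tissues varies enormously between species, even among species
with similar bulk wood density, and that division correlates with
ecological traits such as plant height, leaf area per sapwood area
(LA/SA), and twig stiffness (modulus of elasticity, MOE). twigwood
implements the full measurement-and-analysis chain for this kind of
study:

1. **Stereology** — estimating tissue area fractions from a labeled
   cross-section with a systematic point grid (point hits / total
   points);
2. **Vessel morphometrics** — per-conduit lumen areas, the 15-µm
   small-conduit partition, and the population statistics `A` (mean
   lumen area, mm²), `N = VLF / A` (vessels per mm², with VLF the vessel
   lumen fraction), `S = A / N` (mm⁴), and the hydraulically weighted
   diameter `D_H = Σd⁵ / Σd⁴`;
3. **Derived traits** — wood density by Archimedes displacement, pith and
   sapwood areas as ellipses, SLA and LA/SA, three-point-bending MOE, and
   the composite fractions (total parenchyma, total fibre, total vessel,
   wall);
4. **Statistics** — species means, trait summaries with the
   zero-exclusion rule for n-fold variation, and pairwise correlation
   matrices where the test is gated by Shapiro–Wilk normality (Pearson
   when both traits screen normal, Spearman otherwise);
5. **Synthetic data** — labeled wood mosaics with pixel-exact ground
   truth, and multi-species trait tables with controlled marginals and
   correlation structure, so that every stage can be validated without
   micrographs.

## Stereological estimation

`overlay_grid()` lays a square lattice of points (default spacing 300 px,
matching the classical protocol of 84.3 µm point spacing at 0.281 µm/px)
over a `labeled_section`, `count_points()` tallies the tissue under each
point, and `fractions_from_counts()` converts tallies to fractions with a
binomial standard error `sqrt(p(1-p)/n)`. Design choices:

* Points sit on pixel centres and take the label of their pixel. Labels
  are exhaustive and mutually exclusive, so no boundary interpolation is
  needed; how a human annotator would adjudicate boundary-straddling
  points is unknowable, and the pixel-label rule is this package's
  convention.
* Points on `PITH` or `OUTSIDE` pixels are excluded from the total: the
  fractions describe wood between pith and bark only.
* A minimum of 300 analysed points is enforced (error in strict mode,
  warning otherwise), following the source protocol.
* The grid offset defaults to (0, 0) and can be randomized (seeded) —
  with a uniformly random offset the estimator is exactly unbiased, which
  the test suite verifies to within 0.005 per tissue over 200 offsets.

The binomial standard error treats grid points as independent, which is
approximately right when the grid spacing exceeds the largest single
structure. The acceptance suite checks 3-SE coverage at the oracle
fraction (≥ 99 %) with spacing 64 px against structures no wider than
60 px.

## Vessel morphometrics

`extract_vessels()` finds 4-connected components of vessel-lumen pixels
(hand-written run-merging union-find; an independent implementation
cross-checks it in the tests). Per component it records area,
circle-equivalent diameter `2·sqrt(area/π)`, and maximum Feret diameter
(maximum pairwise distance over the convex hull of pixel centres, plus
one pixel width for the finite pixel extent). Components are kept when
their centroid lies inside the analysed sector.

Conventions, where the measurement protocol leaves room:

* "Diameter" for `D_H` is the circle-equivalent diameter from lumen
  area — exact for the synthetic discs and the standard convention for
  real vessel lumens.
* The "maximum lumen diameter below 15 µm" rule for small conduits uses
  the maximum Feret diameter with a strict inequality.
* The VLF used in `N = VLF / A` defaults to the grid estimate of the
  cross-section (mirroring the original workflow, where the fraction came
  from point counting) but a pixel-exact or user-supplied fraction is
  accepted.

`D_H ≥ mean(d)` always (weighted power-mean ordering), with equality only
for uniform diameters; `N·A = VLF` and `S = A²/VLF` hold exactly by
construction. Both are enforced property-style in the tests.

## Derived traits

* **Wood density** = oven-dry mass / displaced-water mass (volume via
  Archimedes with water density 1.0 g cm⁻³).
* **MOE**: the source protocol names the three-point bending test and the
  20:1 span-to-diameter rule but not the formula; we use standard beam
  theory, `MOE = slope·span³/(48·I)` with the elliptical second moment
  `I = π·a·b³/64` (`b` in the loading direction), on the whole-twig
  diameters including bark and pith, because that is the segment that was
  bent. Violating the span rule warns (errors in strict mode).
* **SLA** is area per dry mass, so that `LMA = 1/SLA`; the protocol
  sentence that inverts this is treated as a slip because the same text
  defines LMA as 1/SLA.
* **Wall material density** = wood density / wall fraction is labelled an
  approximation throughout: it attributes all dry mass to fibre and
  vessel walls, which is only a plausibility check against the
  ~1.5 g cm⁻³ density of pure cell-wall material.
* **Summaries**: per trait, low / high / mean / n-fold variation, where
  traits with structural zeros (small conduits, mucilage canals, and in
  principle pith area) use the smallest *non-zero* value and the mean over
  bearing species only, with the bearing count reported. Display rounding
  follows the conventional table style (fractions 2 decimals, n-fold 1
  decimal).

## Correlation workflow

`correlation_matrix()` computes full Pearson and Spearman matrices
(pairwise-complete, per-pair n reported, average ranks for ties) plus the
headline matrix in which each pair carries Pearson's r if **both** traits
pass the Shapiro–Wilk screen at α = 0.05 and Spearman's ρ otherwise. The
gate direction is the conventional one (normal ⇔ p > α); the protocol
text that appears to invert it is internally inconsistent with running
non-parametric tests on the non-normal traits. No multiple-testing
correction is applied — with ~200 pairs the individual significance bands
(α = 0.05/0.01/0.001) are descriptive, not confirmatory — and the test
suite asserts this absence. The workflow's type-I error on independent
normal traits is calibrated at 0.05 ± 0.02 over 1000 simulations.

Log10 transforms are available per trait in `shapiro_normal()` for
re-screening skewed traits; following the source analysis, untransformed
values with non-parametric tests are the default.

## The synthetic-data module

### Labeled sections

`generate_section()` builds a mosaic from a target fraction vector:

* **Rays** as straight bands of the requested width crossing the section
  at randomized oblique angles (slope 0.15–0.45 from vertical). This is
  the Cartesian analogue of the radial ray fan of a pie-shaped sector;
  perfectly vertical bands would correlate entire grid columns and break
  the binomial error model that real, fanned rays satisfy.
* **Vessels** as non-overlapping discs (dart throwing, lognormal diameter
  with mean 40 µm truncated to ≥ 16 µm) with a wall annulus whose
  thickness realizes the requested wall:lumen ratio; **small conduits**
  as discs strictly below 15 µm; **mucilage canals** as 60 µm discs.
  Larger disc classes are placed first.
* **Axial parenchyma** as clipped circular patches filling leftover
  space.
* **Fibres** as a hexagonal tessellation of the remainder (20 µm pitch);
  each pixel's normalized hexagonal distance to its cell centre is
  compared with the empirical quantile that splits the remaining area
  exactly into the requested wall and lumen shares — no iterative tuning
  is needed and the split is pixel-exact.

Every realized fraction lands within ±0.02 of its target (discs are
indivisible, so the residual is bounded by half a disc); infeasible
targets (disc coverage beyond the dart-packing limit, or a left-over area
with no fibre target) raise errors naming the offending fraction.
Generation is deterministic given the spec and never disturbs the
caller's RNG state.

The mosaic is a measurement substrate, not a micrograph: there are no
growth rings, no vessel multiples or radial files, no tension wood, no
pith/bark boundary geometry, and tissue boundaries are geometric rather
than cellular. Tests passing on it validate the measurement chain
(sampling, labeling, component extraction, unit handling), not robustness
to real histological noise.

### Species trait tables

`generate_trait_table()` emulates a 69-species, three-site,
three-replicate study:

* **Sites**: 41 tropical rainforest, 11 tropical woodland, 17 temperate
  forest species-at-sites. Small conduits occur in exactly 2 + 10 + 14
  species per site and mucilage canals in 3 rainforest species —
  presence/absence is structural (by design), only the magnitudes are
  drawn from the latent field.
* **Marginals** (`default_trait_marginals()`): for each trait a range
  (low, high), mean, and family — near-symmetric scaled Beta
  (concentration 10) for the traits that screen as normally distributed,
  log-scale Beta (concentration 4) for the right-skewed ones. Each
  marginal is calibrated so that at the design sample size the smallest
  and largest stratified quantiles land on (low, high) and the mean
  matches — i.e. the stated range is an *observed-extremes* target, not a
  distribution support, which is how a published range table should be
  read. Values are clamped to the stated range so the bounds also hold
  under plain (non-stratified) copula draws.
* **Dependence**: a Gaussian copula over 16 latent drivers — 13
  observable traits, two composite-split shares, and the canal driver.
  The published-style headline coefficients are mapped to the latent
  scale by `r = 2·sin(πρ/6)` (exact for Spearman targets under monotone
  margins, and a close approximation for the Pearson targets given the
  near-normal margins). Published pairwise matrices are typically
  slightly indefinite; the trait block is repaired by eigenvalue flooring
  with the headline fibre–parenchyma–vessel entries re-pinned each sweep,
  so the repair debits the jointly inconsistent remainder rather than the
  headline trade-off. The two share drivers are grafted on afterwards
  under a Schur-complement feasibility shrink that cannot disturb the
  trait block.
* **Shares**: total parenchyma splits into axial and ray components via
  an axial-share driver, and total fibre into wall and lumen via a
  wall-share driver. Share loadings are not observable pairs; they were
  calibrated once by large-n simulation so that emergent component
  correlations (fibre wall vs density, wall fraction vs MOE) sit near
  the published matrix, and then frozen.
* **Closure**: the eight elementary fractions are renormalized to sum to
  exactly 1 per species (and again per replicate), after which composites
  and the vessel identities `N = VLF/A`, `S = A/N` are recomputed.
* **Replicates**: multiplicative Gaussian noise with coefficient of
  variation 0.1. The emulated study does not report within-species
  replicate variance; 0.1 is this package's stated guess for careful
  anatomical measurements, and it is a spec parameter.
* **Margin sampling** defaults to stratified plotting positions
  (`(rank − 0.5)/n`), so every generated table reproduces the marginal
  range and mean closely; `margin_sampling = "random"` gives plain copula
  draws.

What the emulation reproduces well: the marginal ranges and means, the
fibre–parenchyma trade-off (sample Pearson r across 200 simulated studies
at n = 69 averages within 0.03 of the −0.86 target), the presence counts,
the direction and rough size of the remaining trait correlations, and the
normality split (the traits screening normal on a typical table are
TPF, TFF, FLF, FWF, VLF, TVF, WF — plus occasionally D_H or ray
fraction, the two that sit near the gate in real data too). What it does
not reproduce: correlations involving the conditionally present conduit
fraction are attenuated, because in real data conduit presence tracks
site climate while plant size traits differ by site, and the generator
draws size traits without site effects; and the TPF row of the published
matrix is jointly inconsistent with the pinned −0.86 trade-off, so its
repaired entries (e.g. TPF–MOE) run ~0.05–0.08 weaker than printed.

## Problem sizes and numerical choices

The test and acceptance runs use 960×960 px sections at 1 µm/px (≈ 0.92
mm², ~100 vessels, ~160 small conduits — comfortably inside the 30–500
vessels-per-section envelope of real sectors), 200 grid offsets at 64 px
spacing (225 points each), 200 simulated studies for correlation
recovery, and 1000 replicates for the type-I calibration. These sizes
give Monte-Carlo standard errors several times smaller than the
tolerances being checked. Tolerances: ±0.02 for realized section
fractions (above grid-sampling noise at 300 points), ±0.005 for
estimator bias, the 95 % Fisher sampling interval at n = 69 for
single-study correlation reproduction, and 0.05 absolute for marginal
summaries driven by extreme order statistics at n = 69.

Degenerate inputs are handled explicitly: empty masks, constant vectors,
zero-variance traits (dropped with a warning), all-zero traits (NA
summary row), a single bearing species (pinned to the marginal mean),
empty vessel lists, and sub-minimum point counts all have defined
behaviour and tests.

## Ingesting real data

`read_label_map()` accepts any indexed 8-bit PNG plus a JSON sidecar
mapping palette indices to tissue labels and recording the scale;
`read_trait_dataset()` reads CSV or XLSX trait tables through an explicit
column mapping onto the standard abbreviations (APF, RPF, TPF, FLF, FWF,
TFF, VLF, VWF, TVF, CF, MCF, WF, A, N, S, Dh, PA, WD, H, MH, MOE, LASA).
`run_pipeline()` accepts such a table in place of the simulated one and
runs the identical aggregation, summary and correlation stages.
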