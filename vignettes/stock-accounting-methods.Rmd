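---
title: "Methods: LULC-stratified aboveground carbon and nitrogen accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LULC-stratified aboveground carbon and nitrogen accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(savstocks)
```

## The accounting model

savstocks implements the standard plot-based, LULC-stratified
estimator of aboveground carbon and nitrogen stocks for savannah
landscapes. The chain is:

1. **Species fractions.** Stem-wood samples give per-species mean
   fractions of C and N in dry matter. A census species not in the
   trait table receives the overall mean fraction; with the packaged
   18-species table those fallbacks are 0.4701 (C) and 0.00229 (N).
   The overall mean is, by default, the *unweighted* mean of the
   per-species means. The alternative — weighting species by their
   sample counts — is available via `weighting = "samples"` in
   `traits_table()` and gives 0.47001/0.0022550 for the packaged
   table; the unweighted convention is the default because it treats
   the species, not the sampling effort, as the unit, and because it
   is the convention under which the packaged table's published
   overall values are internally consistent.
2. **Biomass.** An allometric model maps (DBH, height, wood density)
   to oven-dry aboveground biomass in kg. Models live in a registry
   and are routed species-first (palms such as *Phoenix reclinata*
   and *Borassus flabellifer* violate the D²H scaling of
   dicotyledonous trees and get a linear-in-D²-form model), then by
   LULC class, then a default.
3. **Stocks.** Tree stocks are fraction × biomass (kg); plot stocks
   are sums converted to Mg; class densities are plot-density means
   with standard error SD/√np; class totals are density × class area;
   category and landscape totals are sums with root-sum-of-squares
   SEs (classes treated as independent strata).
4. **Tier 1 comparison.** Each class's effective fraction
   ΣC/ΣB — a biomass-weighted mean, which is the correct weighting
   because density itself is biomass-weighted — is compared with fixed
   coefficients 0.47 and 0.5 through the relative error
   100·(c/f − 1).

### Assumptions

* One census row is one stem ≥ 5 cm DBH; multi-stemmed individuals
  are recorded per stem.
* Stem-wood fractions at breast height represent the whole
  aboveground compartment; bark/branch/leaf variation is not
  modelled.
* No uncertainty is propagated from allometric-model error or from
  the trait SEs into the stock SEs; ε reflects plot-to-plot sampling
  variance only.
* A single epoch: no change analysis.

## Tunable parameters

| Parameter | Where | Default | Why |
|---|---|---|---|
| `weighting` | `traits_table()` | `"species"` | see above |
| routing order | `model_registry()` | species > LULC > default | palms must win over class models |
| `dbh_range` | `allometric_model()` | [5, 100] cm | census threshold to typical fitting range; out-of-range DBH extrapolates with a warning rather than failing, since real censuses exceed fitted ranges |
| `tol_pp` | `tier_report()` | 0.02 pp | printed error percentages carry 2 decimals, so 0.02 is the resolution at which a published 0.5/0.47 pair can be called inconsistent |
| `nb_size` | `default_stand_spec()` | 5 | moderate overdispersion of stems per plot; class min/max density ranges in savannah inventories imply strong between-plot variability |
| `wood_density_sigma` | `default_stand_spec()` | 0.05 | ±5% lognormal within-species wood-density noise |
| `resolution` | `generate_class_map()` | 30 m | Landsat-like grid |

Units are fixed: fractions are proportions internally (percent only at
CSV boundaries), biomass kg at tree level, stocks Mg from plot level
up, densities Mg/ha, areas ha.

## The synthetic-stand generator

The generator emulates a 250-plot campaign over eight LULC classes
(30 × 30 m plots in forest, grassland and cropland; 100 × 100 m in
settlements; 10 × 20 m in agroforestry and plantation; 27.26 ha
sampled in total):

* **Traits.** Per species, exactly the published number of samples,
  drawn from a normal with the published mean and SD = SE·√n,
  truncated to the published [min, max] — the simplest distribution
  consistent with all four printed statistics.
* **Stems per plot.** Negative binomial with mean stems_per_ha × plot
  area. Stem rates use published figures where they exist (1397/ha
  riparian, 300/ha cashew) and field-plausible values elsewhere.
* **DBH.** Lognormal truncated to a class-specific range starting at
  the 5 cm census threshold.
* **Height.** H = 1.3 · D^0.65 · exp(ε), ε ~ N(0, 0.15²) — a
  savannah-plausible allometry (≈ 6.6 m at 12 cm DBH).
* **Wood density.** Species mean times mean-one lognormal noise.
* **Class map.** Cell counts rounded from the class areas, laid out
  as contiguous runs along a snake scan in seeded order; cells beyond
  the classified area are no-data (water, roads, bare land).

Because every ingredient has closed-form moments (truncated-lognormal
DBH moments; lognormal noise factors), the expected carbon density of
each class is computed analytically by `expected_stock_density()`, and
`calibrate_registry()` rescales each class's allometric scale
coefficient so that this expectation equals the class's target density
(the reference class densities shipped with the package; the
Plantation target is its reference total divided by its area because
the reference splits that class by planted species). Biomass is linear
in the scale coefficient, so calibration is exact, and the analytic
expectation — not a Monte-Carlo constant — is the ground truth that
recovery tests compare estimates against.

What the generator does *not* emulate: spatial autocorrelation between
plots, species–size interactions (all species share a class's DBH
distribution), measurement error in DBH/height, and the classifier
behind a real LULC map. Passing recovery tests therefore show that the
estimators are unbiased and correctly calibrated under the assumed
sampling model, not that any particular field campaign satisfies that
model.

## Numerical choices and degenerate inputs

* SE of an n = 1 summary (single sample, single plot) is reported as
  0 with a warning rather than NA, keeping aggregation total.
* Treeless plots are legitimate zero-density observations; class
  minima near zero require them.
* Empty censuses give density 0, but IVI on an empty census is an
  error (the index is undefined without stems).
* IVI output is sorted by descending IVI with alphabetical
  tie-breaks, so output order is deterministic.
* Species matching is case-insensitive and whitespace-collapsed; open
  nomenclature ("Ficus sp") matches literally.
* Truncated samplers use the inverse-CDF method, so they are exact
  and cheap even for narrow envelopes.
* Class-map cell counts use `round()`, bounding the per-class area
  error by half a cell; an area smaller than half a cell is an error
  ("grid too coarse") rather than a silently dropped class.

## Design decisions that were genuinely open

* **Mean of plot densities vs pooled ratio.** Class density averages
  per-plot densities (matching the ± SD/√np error form); stem density
  uses the pooled-ratio estimator (stems over pooled area), which is
  how per-ha stem counts are conventionally quoted. Within a class
  all plots share one size, so the density conventions coincide
  there.
* **Grand-total SE.** Root-sum-of-squares over classes, treating
  classes as independent strata. Published tables of this kind do not
  always state their rule, and some printed SEs cannot be reproduced
  by any simple rule; no package output depends on matching them.
* **Tier errors from published pairs.** When both the 0.5 and 0.47
  errors of a class are supplied, the package recomputes the 0.47
  error from the 0.5 one and flags the pair if they disagree beyond
  `tol_pp` — published pairs are occasionally typographically
  inconsistent, and silent acceptance would poison downstream use.
* **Raster stack.** Maps are plain matrices with grid metadata,
  written as ESRI ASCII grid — a text format every GIS ingests — with
  class-constant density surfaces as the legend semantics. Per-pixel
  biomass modelling is out of scope.

## Problem sizes in the shipped tests

Unit and property tests run on toy censuses (≤ a few dozen stems) and
single-seed draws of the default 250-plot design (~6000 stems).
The parameter-recovery suite uses 200 seeded replicates of the
two informative medium-size classes (cropland, 80 plots; savannah
woodland, 27 plots) and checks that the estimated class density falls
within 3 estimated SEs of the analytic truth in at least 95% of
replicates; observed coverage is ≈ 97–99%.

## Known limitations

* Allometric coefficients shipped as defaults are generic
  placeholders (a pantropical power-product form and a generic palm
  form); serious use requires locally fitted equations in the
  registry, which is the point of making it a config file.
* The calibration requires each class's species to route to a single
  model; mixed-model classes must be calibrated by hand.
* No spatial coordinates within plots and no plot-count planning.
* Nitrogen has no fixed-coefficient analogue of the Tier 1 carbon
  comparison; none is defined for it.
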