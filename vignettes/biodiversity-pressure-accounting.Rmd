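---
title: "Methods: spatial biodiversity-pressure accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial biodiversity-pressure accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BiodivPressure)
```

## The model

The package quantifies the pressure that crop cultivation places on
terrestrial vertebrates, and traces that pressure through trade to the
countries that ultimately consume the food. Everything is built from
four per-cell surfaces on an equal-angle grid: harvested area HA (ha),
fresh-weight yield (t/ha), species richness SR (the count of vertebrate
ranges overlapping the cell), and the derived production
P = yield × HA, optionally converted to dry weight.

The *affected species range* per cell is ASR = HA × SR (species·ha): an
area-weighted count of potentially affected ranges, not a number of
species (the same species is counted in every cell it overlaps; the
quantity is meaningful relative to other cells and countries, not in
absolute terms). The *biodiversity pressure* BP = ASR / P (species·ha
per tonne) relativises that extent by the food produced on it, so a
highly biodiverse but low-yielding cell scores higher than an equally
biodiverse productive one.

Country aggregation uses fractional-coverage zonal statistics: cell
values enter a country's totals weighted by the fraction of the cell
inside the country. The country-level per-tonne pressure is the
*production-weighted* mean of cell BP,

$$\mathrm{BP}_{c,i} \;=\; \frac{\sum_{l \in i} P_{c,l}\,\mathrm{BP}_{c,l}}
                               {\sum_{l \in i} P_{c,l}},$$

and the national production pressure is
$\mathrm{BP}_{\mathrm{prod}\,c,i} = \mathrm{BP}_{c,i} \times P_{c,i}$.
Substituting the definitions collapses this composition to the
country-summed ASR layer, $\sum_l P_l (\mathrm{ASR}_l / P_l) = \sum_l
\mathrm{ASR}_l$ (over cells with nonzero production); the test suite
verifies the identity to a relative $10^{-9}$, and it serves as the
package's strongest internal consistency check because the two sides are
computed along different code paths.

The consumption side decomposes a focal country's supply of each crop:

$$\mathrm{BP}_{\mathrm{cons}\,fc,c} \;=\; C^{\mathrm{dom}}_{fc,c} \times
  \mathrm{BP}_{fc,c} \;+\; \sum_i T_{i,fc,c} \times \mathrm{BP}_{c,i},$$

with $C^{\mathrm{dom}}$ = production − exports (clamped at zero, the
shortfall logged: exports exceeding production indicate re-exports the
model cannot attribute) and $T_{i,fc,c}$ the import tonnage from origin
$i$. Using the production-weighted country BP for the origins encodes
the assumption that exports are sourced proportionally to where
production is largest within the exporting country. Imports from origins
with no recorded production of the crop cannot be priced in pressure
terms; their tonnage is reported as unattributed rather than silently
dropped.

## Parameters that matter

| parameter | units | default | rationale |
|---|---|---|---|
| `cellSize` | degrees | 5/60 (5 arcmin) | the resolution of the global circa-2000 crop grids; the synthetic test grid uses 7.5° for speed |
| weight basis | – | dry | dry tonnes make crops with very different water contents comparable; one pipeline-level switch (`weightBasis`) governs production *and* trade so the additive consumption decomposition stays in one unit system |
| water content | % of fresh mass | per crop | dry tonnes = fresh × (1 − w/100) |
| zero-production tolerance | t | 1e-9 | cells with production below this are masked in BP; resampling float noise must not create astronomically large per-tonne pressures |
| Earth radius | m | 6,371,007.2 | authalic sphere; sub-0.3 % cell-area error versus an ellipsoid, standard for coarse equal-angle accounting |
| exclusion list | country ids | empty | territories outside the analysis scope are configuration, not code |

A note on cell areas: spherical geometry gives ≈ 8.6 × 10³ ha for a
5-arcmin cell at the equator (a ~9.3 km square), which the geometry
tests assert against an independent numerical integral of
$R^2\cos\varphi$.

## Grid alignment

Crop and richness grids rarely match; `alignToGrid()` interpolates a
layer at the target's cell centres (corner registration, row 1
northmost, values at centres). Bilinear is the default for continuous
surfaces; which grid is the target is explicit configuration
(`targetGrid`), defaulting to the richness grid. Numerical choices:

- a target cell is masked only when its entire 2 × 2 stencil is masked;
  otherwise masked neighbours are dropped and the weights renormalised,
  so sparse crop maps do not lose their coastlines;
- the output is a convex combination of unmasked stencil values — no
  overshoot beyond the stencil extrema (property-tested on random masked
  layers);
- target centres beyond the outermost source centres but inside the
  source extent get constant edge extrapolation; centres outside the
  extent are masked; fully disjoint grids are an error;
- bilinear resampling is *not* mass-conserving. Totals before and after
  are logged (run log, or `options(BiodivPressure.verbose = TRUE)`) and
  deliberately not renormalised — rescaling would silently distort the
  yield–area relationship.

Richness is integer-valued on input but may become fractional after
resampling; downstream algebra never needs integrality, so real-valued
richness surfaces are accepted.

## The synthetic world

`generateWorld()` emulates the statistical shape of the real inputs —
sparse non-negative harvested-area fractions bounded by the spherical
cell area, smooth positive yield surfaces, a spatially autocorrelated
integer richness surface (smoothed Gaussian noise, rescaled and
rounded), a contiguous-country partition grown by frontier accretion
from random seed cells (ties to the lowest country id), fruit/vegetable-
like water contents, and sparse trade whose origins actually produce the
crop and whose exports never exceed production (so the closed-world
conservation identity holds without clamping). One root seed is fanned
out to named substreams, so adding a generator field never perturbs the
other draws and fixtures stay stable.

Default study conditions: a 24 × 48 global grid (7.5° cells), 3
countries, 4 crops, richness 10–200 species, ~35 % of cells cultivated
per crop, yields 2–20 t/ha fresh, water contents 70–95 % (typical for
fruits and vegetables), and trade on ~40 % of feasible partner pairs.
These sizes keep the full pipeline and the brute-force oracles well
under a second per run while leaving every code path (masking, fractional
coverage, trade attribution) exercised.

What the generator does *not* emulate: realistic geography or climate
suitability, correlation between richness and agro-ecological
suitability, heavy-tailed trade-flow size distributions,
processed-commodity conversion, or real-world pressure magnitudes.
Passing tests therefore demonstrate the *accounting* is correct — the
algebra, the weighting, the masking and the trade attribution — not that
any real-world number is reproduced; headline values from the global
datasets (registered-access range maps, primary-equivalent trade
matrices) are outside desk scale.

`generateKnownBPWorld()` inverts the model for testing: uniform unit
yield, zero water content and per-country uniform richness equal to the
target make every cell's BP equal the country target, so any correct
weighting scheme must recover the targets exactly — a parameter-recovery
check of the full pipeline rather than of one function.

## Design choices made where the design was open

- **Denominator basis of BP.** Whether published per-tonne pressures
  used fresh or dry tonnes is ambiguous; the country-level weighting is
  explicitly dry. The package uses one `weightBasis` switch (default
  dry) applied consistently to production, BP, and trade tonnes, and
  records it in the output metadata, making either reading reproducible.
- **Zero production ≠ zero pressure.** Countries with no production of a
  crop get an empty field in output tables, never 0; BP-masked cells are
  excluded from both numerator and denominator of the weighted mean but
  still contribute to ASR totals (ASR is production-independent).
- **Coverage fractions.** Arbitrary fractions in (0, 1] are supported in
  the zones table; the bundled label-raster path assigns whole cells
  (coverage 1). Exact polygon–cell intersection would need a geometry
  engine and is out of scope; the zonal statistics are agnostic to how
  the fractions were obtained.
- **Ranking.** Dense descending ranks, ties sharing a rank and ordered
  lexicographically by id — deterministic output for regression tests.
- **Byte-stable outputs.** CSVs use a fixed column order and scientific
  notation with 9 significant digits; two runs on the same fixture are
  byte-identical, which the acceptance suite checks with a raw file
  comparison. Log-scale transforms seen in typical visualisations are
  presentation-only and never applied to stored values.

## Limitations

ASR double-counts wide-ranging species across cells by construction and
weights all species equally; the pressure metric measures potential
exposure of ranges, not demographic impact. Trade attribution uses one
country-level BP per origin — sub-national sourcing heterogeneity is
deliberately collapsed by the production-weighting assumption.
Re-exports are clamped, not redistributed. The ASCII-grid reader/writer
handles single-band layers only.
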