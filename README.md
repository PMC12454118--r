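# BiodivPressure

Spatial accounting of the biodiversity pressure exerted by crop
cultivation, and of how that pressure is redistributed by international
trade.

## The problem and who this is for

Growing fruit and vegetables takes land, and where that land overlaps the
ranges of many wild vertebrates, production puts pressure on biodiversity.
For food-systems researchers and environmental-footprint analysts this
package turns gridded agricultural data (harvested area and yield per
grid cell), a species-richness surface, a country partition of the grid,
and bilateral trade tables into comparable country- and crop-level
pressure indicators — including the pressure a country *imports* through
its food supply, not just the pressure it generates at home.

## The metrics

All layers live on an equal-angle (latitude–longitude) grid; cell areas
come from the spherical band formula on the authalic sphere
(R = 6,371,007.2 m). For crop *c*, grid cell *l* and country *i*:

- **Affected species range** ASR<sub>c,l</sub> = HA<sub>c,l</sub> × SR<sub>l</sub>
  (harvested hectares times vertebrate species richness; species·ha).
- **Production** P<sub>c,l</sub> = yield × HA, converted to dry weight by
  × (1 − water&nbsp;content/100); tonnes.
- **Biodiversity pressure** BP<sub>c,l</sub> = ASR<sub>c,l</sub> / P<sub>c,l</sub>
  (species·ha per tonne); cells with production below a tolerance are
  masked, not infinite.
- **Country mean** BP<sub>c,i</sub> = Σ<sub>l∈i</sub> P<sub>c,l</sub> BP<sub>c,l</sub> / Σ<sub>l∈i</sub> P<sub>c,l</sub>
  — a production-weighted mean over the country's cells with fractional
  cell coverage supported.
- **Production pressure** BP<sub>prod c,i</sub> = BP<sub>c,i</sub> × P<sub>c,i</sub>,
  which algebraically equals the country-summed ASR.
- **Consumption pressure** BP<sub>cons fc,c</sub> = C<sup>dom</sup> × BP<sub>fc,c</sub> + Σ<sub>i</sub> T<sub>i,fc,c</sub> × BP<sub>c,i</sub>,
  where C<sup>dom</sup> = production − exports and T are import flows;
  origin pressures use the production-weighted country BP, encoding the
  assumption that exports come from where production is largest.

A seeded synthetic-world generator supplies self-consistent inputs
(sparse harvested-area surfaces bounded by cell area, smooth yields,
spatially autocorrelated richness, contiguous countries, feasible trade)
with analytically known ground truth, so the whole pipeline is testable
without any external datasets.

## Worked example

```r
library(BiodivPressure)

world <- generateWorld(worldConfig(seed = 7))   # 24x48 grid, 3 countries, 4 crops
m <- countryCropMetrics(world$crops, world$richness, world$zones)
head(m, 3)
#>   country   crop production_total    asr_total  bp_mean      bp_prod
#> 1     AAA crop01       2714832589  80312511584 29.58286  80312511584
#> 2     AAB crop01        400109908  12811445313 32.01982  12811445313
#> 3     AAC crop01      13688229383 468146680516 34.20067 468146680516
```

Country AAA produces 2.7 × 10⁹ dry tonnes of `crop01`; that cultivation
overlaps 8.0 × 10¹⁰ species·ha of vertebrate ranges, i.e. 29.6 species·ha
of pressure per tonne. `bp_prod` equals `asr_total` — the identity
Σ P·(ASR/P) = Σ ASR that the test suite verifies to 10⁻⁹.

Consumption-side attribution with the world's trade table (converted to
the same dry-weight basis):

```r
trade <- tradeToDry(world$trade, world$water)
s <- splitSupply("AAA", "crop01", m$production_total[1], trade)
bpCons("AAA", "crop01", s$domestic, m, trade)
#> ConsumptionPressure AAA / crop01: BP_cons 8.17471e+10 species.ha
#>   (domestic 8.03125e+10, imports 1.43462e+09 over 1 origin)
```

Of AAA's total consumption pressure for `crop01`, 98% is generated
domestically and the rest is embedded in imports from its one trade
partner. The batch interface (`runPipeline()`, or the CLI wrapper in
`inst/cli/biopressure.R`) writes per-cell ASR/BP layers, the country ×
crop metrics table, per-focal-country consumption decompositions,
rankings and a run log as byte-stable plain-text files.

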