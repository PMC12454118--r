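Package: BiodivPressure
Title: Spatial Biodiversity-Pressure Accounting for Crop Production and Trade
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Gridded accounting of the biodiversity pressure exerted by crop
    cultivation. Computes the affected species range (ASR, the per-cell
    product of harvested area and vertebrate species richness), the
    per-tonne biodiversity pressure (BP = ASR / production), dry-weight
    production from water-content tables, production-weighted country means
    by fractional-coverage zonal statistics, national production pressure,
    and the trade-partitioned pressure embedded in national consumption
    (domestic supply times domestic BP plus each import flow times the
    origin country's BP). Includes equal-angle raster geometry with
    spherical cell areas, bilinear/nearest-neighbour grid alignment,
    plain-text raster and table I/O, a seeded synthetic-world generator
    with analytically known ground truth, and a batch pipeline with a
    command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'grid-geometry.R'
    'io.R'
    'trade.R'
    'pressure.R'
    'zonal.R'
    'synthetic-world.R'
    'pipeline.R'
    'resample.R'
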