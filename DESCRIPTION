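Package: pjcarbon
Title: Carbon Stock Accounting for Pinon-Juniper Woodland Encroachment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Plot- and landscape-scale carbon accounting for semi-arid
    woodlands undergoing pinon-juniper encroachment. Converts understory
    cover and tree root collar diameter to biomass and carbon with
    published allometric equations, builds per-plot carbon stock ledgers
    (tree, sagebrush, grass, duff/litter and mineral soil pools), tests
    the spatial distribution of trees and soil carbon with Moran's I and
    average nearest neighbor statistics, models annual aboveground carbon
    accumulation from tree establishment dates, scales canopy-delineated
    imagery to landscape carbon stocks, and ships a seeded synthetic stand
    generator (clustered Thomas-process stands, cover fields, soil
    surveys and canopy rasters) so the whole pipeline is testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
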