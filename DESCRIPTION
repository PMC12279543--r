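Package: lakecomposer
Title: Composite Lake Hypsography and Functional Aggregation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models individual lake hypsography from surface area, maximum
    depth and mean depth using the two-parameter Imboden depth-area model,
    and aggregates arbitrary collections of lakes depth by depth into
    composite ("uber") lakes. Computes composite morphometric and
    functional metrics (mean depth, dynamic ratio, epilimnetic area and
    volume fractions, volume-weighted mean temperature), derives thermocline
    depth and atmosphere-isolation profiles from daily depth-resolved
    temperature and ice series, scales volumetric process rates to areal
    bases, assigns lakes to 1-by-1 degree grid cells and label groups,
    clusters composite features by Ward's method with silhouette-based
    selection of the number of clusters, propagates morphometric
    uncertainty by Monte Carlo simulation, and generates synthetic lake
    populations with Pareto size distributions and depth-area scaling for
    testing every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
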