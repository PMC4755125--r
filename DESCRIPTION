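Package: dasypop
Title: Temporally Comparable Random-Forest Dasymetric Population Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds count-preserving ~100 m gridded population surfaces from
    census counts on administrative polygons and covariate rasters, for several
    census years over a fixed target zone set. Census counts are harmonized onto
    the target zones by intersection-area weighting, a Random Forest regression
    of unit-level log population density on zonal covariate means (500 unpruned
    trees, single-observation terminal nodes, all covariates candidate at each
    split) is fitted independently per year, and its pixel-level predicted
    density surface is used as the weighting layer in a dasymetric
    redistribution that conserves every unit total exactly. Includes signed
    distance-to-built-edge and related covariate builders, out-of-bag error and
    permutation importance reporting, the count- and density-scale validation
    metric suite (RMSE, RMSE per area, percent RMSE, MAE, MAD), and a synthetic
    multi-year world generator so the full pipeline is testable without
    restricted census data. Rasters are read and written as single-band ESRI
    ASCII grids and zone sets as GeoJSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    ranger
Config/testthat/edition: 3
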