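Package: hli
Title: Healthy Location Index for Small-Area Environmental Accessibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds an area-level healthy location index from accessibility to
    health-promoting ('goods': green space, blue space, physical-activity
    facilities, supermarkets, fruit and vegetable outlets) and
    health-constraining ('bads': fast food, takeaway, dairy/convenience,
    alcohol, gaming) environmental domains.  Road-network distances to the
    nearest facility are computed from population-weighted centroids of
    small areas; green- and blue-space access uses a raster distance
    transform and the median proximity over each area.  Per-domain ranks are
    summed by polarity, re-ranked, cut into deciles and three access
    categories, and crossed into a nine-class index.  Includes a synthetic
    geography generator with a plantable deprivation-accessibility gradient,
    socio-spatial summary tables, and a reproducible file-based pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    EBImage,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
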