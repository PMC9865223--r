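Package: vegindex
Title: Multi-Temporal Modified Vegetation Indices and Knowledge
    Decision Tree Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for identifying vegetation types from multi-date
    Sentinel-2-style surface-reflectance imagery. Implements typical
    vegetation indices (RVI, DVI, NDVI), uni- and multi-temporal modified
    indices built from red-edge and shortwave-infrared band combinations
    (UTM-DMI, MTM-NDQI, MTM-DSI, MTM-RSI), the standard-deviation-sum
    screening procedure used to select feature band combinations, a
    hierarchical knowledge-decision-tree classifier over the optimal
    feature set, a random-forest comparator, confusion-matrix accuracy
    statistics (overall, producer and user accuracy, Kappa), and a
    synthetic multi-temporal scene simulator emulating seven vegetation
    classes' spectral phenology.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml,
    randomForest,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
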