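Package: townnet
Title: Complete Social Networks of an Aging Township from Ego-Centric Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing the complete discussion network of
    a small community from name-generator survey data on older adults. Provides a
    synthetic township generator with planted ground truth, survey validation and
    category codebooks, the six classic ego-centric network measures (size,
    composition, average closeness, contact volume, density, bridging potential),
    rule-based entity resolution of duplicate alter mentions into canonical
    persons, complete-network centralities (in/out-degree, normalized closeness
    with a disconnected-graph correction, normalized betweenness), Gould-Fernandez
    brokerage roles with district groups, weak/strong component extraction and a
    five-class component typology, and grouped-means reporting tables with one-way
    ANOVA significance and overall mean/SD/skewness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
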