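Package: equirep
Title: Extent and Equality of Protected-Area Networks Along Environmental Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how evenly a network of strict protected areas samples
    the natural conditions of a territory. Protection extent (percent of land
    protected) is paired with a protection-equality index, one minus the Gini
    coefficient of per-bin protection percentages along binned continuous
    environmental gradients or across biogeographical units (ecoregions).
    Includes gridding of vector protected-area records onto a geodesic
    longitude-latitude lattice, percentile-trimmed histogram binning,
    Kendall-tau collinearity pruning, decadal extent-equality trajectories,
    per-cell conservation-priority scores with quantile classification, and a
    random-forest ranking of human drivers of protection placement via
    out-of-bag permutation importance with bootstrap uncertainty. A synthetic
    landscape generator with controllable placement bias provides ground-truth
    inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
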