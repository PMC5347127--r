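Package: pccorrnet
Title: Discriminative Correlation Networks from PCA Loadings (PC-corr)
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers discriminative correlation networks from omic
    sample-by-feature matrices by fusing the loadings of a discriminative
    principal component with pairwise Pearson correlations through a
    minimum operator (PC-corr). Includes the univariate baselines the
    method is compared against (P-value correlation network and P-value
    mutual-information network via the CLR transform), frustration-based
    cut-off diagnostics, leave-one-out cross-validation robustness
    analysis, a synthetic-data generator with planted correlated and
    discriminative feature blocks, and Cytoscape-ready table export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
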