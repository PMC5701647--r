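Package: hemiconn
Title: Hemispheric Asymmetry Analysis of Weighted Brain Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds left and right intrahemispheric weighted brain networks
    from multimodal connectome inputs (ROI time series for functional
    connectivity, streamline counts and region volumes for structural
    streamline-density networks), computes weighted small-world metrics
    (clustering coefficient, characteristic path length, small-worldness
    against degree-preserving rewired nulls, global/local/nodal efficiency)
    with sparsity-threshold integration for the functional arm, quantifies
    lateralization with the AS(X) asymmetry index, localizes lateralized
    connections with a paired network-based-statistic permutation test, and
    relates asymmetry to behavioral scores via covariate-adjusted partial
    correlation. Includes a synthetic cohort generator with known injected
    hemispheric asymmetry for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'nodeTable.R'
    'simulate.R'
    'build.R'
    'metrics.R'
    'asymmetry.R'
    'nbs.R'
    'groupStats.R'
    'io.R'
    'pipeline.R'
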