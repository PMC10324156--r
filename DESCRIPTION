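Package: swreduce
Title: Iterative Reduction of Stepped Wedge Cluster Randomised Trial Designs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for evaluating and iteratively reducing stepped wedge
    cluster randomised trial designs with continuous outcomes. Computes the
    generalised least squares variance of the treatment effect estimator for
    complete and incomplete designs under exchangeable, block-exchangeable
    and discrete-time decay intracluster correlation structures; quantifies
    the information content of centrosymmetric pairs of cluster-period
    cells; greedily removes low-information cell pairs until the treatment
    effect is no longer estimable; and reports precision loss and power
    along the removal path, including a parameter sweep across trial
    configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
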