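Package: wfrecomb
Title: Recombination-Rate Inference from Continuously Observed Wright-Fisher Diffusions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum likelihood estimation of the recombination rate from a
    continuously observed (discretely gridded) Wright-Fisher diffusion of
    haplotype frequencies. Provides the multi-allelic two-locus (and general
    multi-locus) drift and diffusion machinery, an Euler-Maruyama simulator
    with a boundary-safe square-root decomposition of the covariance and
    streaming accumulation of the score and observed-information integrals,
    the boundary-corrected estimator with explosion (infinite-information)
    handling, a likelihood-ratio test for the presence of recombination under
    a chi-squared boundary mixture null, selection-adjusted and joint
    recombination/selection estimators, numeric confounder-robustness checks,
    and a replication harness for the associated simulation study.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
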