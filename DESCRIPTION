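Package: allonet
Title: Allosteric Coupling Analysis on Residue Contact Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts allosteric coupling in proteins from a single static
    structure. A PDB file is converted into a residue-level network whose edge
    weights are perturbation-propagation probabilities derived from
    atom-contact counts, and a repeated stochastic frontier process on that
    network yields allosteric coupling intensities (ACI), source-to-target
    allosteric pathway ensembles with per-residue importance scores, allosteric
    hotspots found by ACI gradient-following, and all-pairs coupling maps.
    Includes utilities to compare predicted coupling maps with NMR chemical
    shift covariance analysis (CHESCA) and synthetic structure generators for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
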