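Package: dbsfield
Title: Field-Cable Modeling of Directional Deep Brain Stimulation Electrodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-element volume-conductor models of current-controlled deep
    brain stimulation (DBS) through a segmented directional lead, coupled to
    multi-compartment myelinated axon cable models. Implements five current
    source representations for the active contact (point current, boundary
    current, current density, two-solve electric potential, floating
    potential) combined with explicit or boundary-condition representations
    of the contacts and shaft, yielding a matrix of fifteen volume-conductor
    model variants solved on a shared tetrahedral mesh. Extracellular
    potentials drive myelinated axon populations to activation thresholds by
    bisection, from which current-distance curves, active-axon counts and
    activation volumes are computed and compared across model variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    graphics,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    xml2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
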