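Package: pliincline
Title: Nerve Fibre Inclination Mapping from 3D Polarised Light Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes out-of-plane nerve fibre inclination maps from 3D
    polarised light imaging (3D-PLI) measurements of histological brain
    sections. Extracts transmittance, in-plane direction and retardation
    maps from polariser rotation series by discrete harmonic analysis,
    estimates myelination thresholds from histogram curvature, quantifies
    transition zones between highly and lowly myelinated tissue by
    bootstrapping, builds a high-myelination probability map with sigmoid
    transition zones, and evaluates unweighted, transmittance-weighted and
    linearly combined inclination models. A forward-model phantom generator
    with per-pixel ground truth makes the whole pipeline testable without
    measurement data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
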