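Package: redoxmap
Title: Rigid-Body Conformational Sampling and Electron-Transfer Mapping of
    Redox Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exhaustive rigid-body conformational sampling of a mobile redox
    protein over the surface of a binding partner, with steric screening by a
    repulsive quartic van der Waals potential and a reduced side-chain atom
    set.  For every sampled centre-of-mass placement the package records the
    minimal cofactor edge-to-edge distance at steric contact, converts it to a
    non-adiabatic electron-transfer rate with the Moser-Dutton distance ruler
    and the Marcus activation term, and summarises the resulting functional
    epitope (upper-limit rates, epitope sizes, distance and rate
    distributions).  Binary, ternary and multidomain-ensemble complexes are
    supported, together with a synthetic toy-structure generator that provides
    analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
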