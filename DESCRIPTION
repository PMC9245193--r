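Package: mistent
Title: Configurational Entropy of Conformational Ensembles and Its
    Experimental Proxies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates molecular configurational entropy from conformational
    ensembles using the maximum information spanning tree (MIST)
    approximation in bond-angle-torsion (BAT) internal coordinates, and
    relates entropy changes upon binding to three experimentally accessible
    proxies of protein dynamics: methyl and backbone-NH Lipari-Szabo order
    parameters and B-factor-derived quasi-harmonic entropies.  Includes
    histogram estimators for one- and two-dimensional differential
    entropies and mutual information, subset decompositions and
    vibration-suppressed (coarse-binned) entropies, a regression and
    undersampling comparison pipeline, and a synthetic-ensemble generator
    with analytically known entropies for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
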