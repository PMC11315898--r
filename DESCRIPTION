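Package: xlassemble
Title: Cross-Link-Restrained Rigid-Body Docking and Combinatorial Assembly of Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative modelling toolkit for multi-subunit protein complexes
    restrained by cross-linking mass spectrometry (CLMS) data. Scores models by
    the fraction of cross-links whose Calpha-Calpha distance falls below a
    satisfaction threshold, performs cross-link-restrained rigid-body pairwise
    docking over a deterministic rotation grid, hierarchically assembles N
    subunits from pairwise docking configurations by beam search over a
    link-supported spanning tree, and validates models against small-angle
    X-ray scattering (SAXS) curves via Debye-formula profiles, least-squares
    scale fitting with chi-square, and Guinier analysis. Also provides Kabsch
    superposition, Shrake-Rupley solvent-accessible surface area, buried
    interface area, protein isoelectric point, and a synthetic-fixture
    generator that emulates a hetero-octameric Mis18-like assembly (a linear
    array of Yippee-like globular domains flanked by two triple-helix bundles)
    with simulated cross-links and noisy SAXS curves for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
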