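Package: solvaxs
Title: Explicit-Solvent Prediction of SAXS/WAXS Curves from Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes small- and wide-angle X-ray scattering (SWAXS) curves of
    biomolecules from explicit-solvent trajectories without hydration-layer or
    excluded-volume fitting parameters. A star-shaped envelope built from a
    recursively subdivided icosahedron separates the solute plus its hydration
    shell from bulk solvent; buffer-subtracted intensities are assembled from
    Cromer-Mann atomic form factors with an electron-withdrawing correction
    for water, orientationally averaged by spiral quadrature. Includes
    experimental-curve fitting with error-weighted and log-space metrics,
    Guinier analysis, structure clean-up rules for crystallization agents and
    selenomethionine, and a synthetic solute/water system generator so the
    whole pipeline is testable without molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    generics,
    ggplot2,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
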