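Package: hydratherm
Title: Hydration Equilibrium Thermochemistry of Cationized Nucleobases
Version: 0.1.0
Authors@R: person("HPMS", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for gas-phase hydration equilibria of
    sodiated and potassiated nucleic acid bases measured by pulsed ion-beam
    high-pressure mass spectrometry. Simulates arrival-time distributions
    under a detailed-balance kinetic scheme, reduces them to peak areas with
    Poisson counting uncertainties, verifies equilibrium attainment from the
    residence-time constancy of intensity ratios, computes equilibrium
    constants referenced to a 1000 mbar standard state, extracts hydration
    enthalpies and entropies by weighted van't Hoff fits with full
    uncertainty propagation, and analyses the linear correlation between
    water binding energies and metal-ion affinities, including
    tautomer-population-weighted affinities for cytosine mixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
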