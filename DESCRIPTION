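Package: radscav
Title: Radical-Scavenging Kinetics, DPPH Dose-Response and Geometry Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing toolkit for computational antioxidant studies.
    Screens candidate radical-scavenging channels (formal hydrogen transfer,
    radical adduct formation, single electron transfer) by reaction free
    energy, computes conventional transition-state-theory rate constants with
    Wigner or Eckart tunneling corrections and reaction-path degeneracy,
    applies Stokes-Einstein/Smoluchowski/Collins-Kimball diffusion corrections
    for condensed media, and aggregates channels into branching ratios and
    overall rate constants following the QM-ORSA scheme. Also provides DPPH
    plate analysis (scavenging percentage, censored EC50 estimation via a
    four-parameter logistic fit) and internal-coordinate molecular geometry
    metrics (bonds, angles, dihedrals, mean-plane r.m.s. deviation,
    plane-plane angles, hydrogen-bond geometry, crystal-vs-optimized
    comparison), plus seeded simulators for every input type.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
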