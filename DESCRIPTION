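Package: memwash
Title: Kinetics of Membrane-Mediated Potentiator Washout
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing the washout kinetics of lipophilic channel
    potentiators that reach their binding site through the membrane. Implements
    a three-state (water/membrane/protein) compartmental model of drug washout
    with closed-form and numerical solvers, its two limiting kinetic regimes
    and the effective single-exponential time constant; a synthetic inside-out
    patch-clamp trace generator with per-analog presets; potentiation and
    decay-constant estimation from current traces; a logP-based scaling law
    linking substituent hydrophobicity to the membrane dissociation rate, with
    a ratio-loss one-parameter fit; and a minimal weighted-ensemble rare-event
    sampler on a one-dimensional toy landscape with brute-force first-passage
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
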