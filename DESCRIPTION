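Package: thrombosim
Title: Continuum Simulation of Arterial Platelet Thrombus Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates platelet thrombus formation in arterial flow with a
    continuum adsorption model. Implements the one-dimensional spatial
    adsorption equation family (multilayer, single-site and
    non-saturating variants) with traveling-front diagnostics, and a
    two-dimensional simulator that couples a shear-dependent
    adhesion-convection equation for platelet concentration to
    incompressible channel flow solved by Chorin projection on a
    staggered grid, with the growing thrombus treated as a rigid
    obstacle once concentration crosses a threshold. Includes wave
    velocity, thrombus area and shape metrics, CSV/VTK field output,
    a YAML configuration layer and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
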