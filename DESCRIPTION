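Package: tensiletwin
Title: Digital Twin of a Magnetically Actuated Uniaxial Tensile Tester for Soft Tissues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a closed-loop uniaxial tensile tester in which an
    electromagnet pulls a ferromagnetic bead glued to a soft specimen while a
    linear CCD tracks the bead shadow. Provides the exponential coil force
    law and its inverse, Kelvin-Voigt and strain-stiffening sample mechanics,
    an adaptive pole-placement PID controller with anti-windup, a sub-pixel
    shadow-tracking sensor model with noise, delay and quantization, a seeded
    closed-loop integrator, stress-strain analysis (windowed Young's modulus,
    hysteresis, preconditioning convergence, strain-rate summaries), and an
    iso-strain multilayer composite model of the esophageal wall.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
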