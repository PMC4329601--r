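Package: anthroinertia
Title: Geometric Human Body Segment Inertial Parameters from Anthropometric
    Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computes body segment inertial parameters (mass, center of mass,
    inertia tensor) for a personalised human model built from 95
    anthropometric measurements, following Yeadon's geometric method. The
    body is modelled as 11 rigid segments composed of 40 stadium solids and
    a semi-ellipsoidal cranium, posed by 21 joint angles on a kinematic
    tree. Inertial properties of any solid, segment, combination, or the
    whole body can be expressed about arbitrary points in arbitrary frames.
    Includes YAML measurement/configuration file readers, a synthetic
    measurement generator, a numerical quadrature oracle for validating the
    closed-form solid properties, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
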