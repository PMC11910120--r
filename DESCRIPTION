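Package: dyefront
Title: Dye-Front Tracking and Pseudo Diffusion Coefficients for Dissolved
    CO2 in Hydrogels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the indicator-based analysis of dissolved carbon
    dioxide diffusion in pH-indicator-doped hydrogel columns.  Detects the
    blue/yellow bromothymol-blue interface in time-lapse vial images
    (rectification, saturation extraction, Otsu binarisation, sub-pixel
    row-profile localization), converts interface tracks to interface
    velocities and pseudo diffusion coefficients via the square-root-of-time
    law, and aggregates replicate vials.  Includes a carbonate-equilibrium
    speciation solver, 1-D diffusion generators (closed-form and finite
    difference), and a seeded, ground-truthed synthetic image generator that
    emulates the optical setup (yellow backlight filter, illumination
    gradient, sensor noise, dropping meniscus) so the full pipeline is
    testable without original imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    EBImage,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
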