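Package: bladdervol
Title: Non-Imaging Three-Beam Ultrasound Bladder Volumetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates bladder volume from three A-mode pulse-echo
    ultrasound traces without image formation. Echo envelopes are
    extracted with a discrete Hilbert transform, near- and far-wall
    echo times are converted to ranges via the speed of sound, and a
    closed-form circumscribed-sphere construction turns the three
    far-wall ranges plus the probe standoff into a sphere radius and
    volume. Includes a seeded A-mode phantom simulator that emulates
    a water-tank balloon experiment, batch error-analysis tools and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
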