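Package: vescav
Title: Cavitation Microbubble Dynamics and Wall Stresses in Elastic Microvessels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator for ultrasound-driven microbubble cavitation
    confined inside an elastic blood vessel. Provides a Keller-Miksis radial
    dynamics tier for free spherical bubbles, a half-symmetry fluid-structure
    interaction finite-element tier (incompressible blood on a moving mesh,
    lumped gas bubble, nearly incompressible linear-elastic vessel and tissue
    with an absorbing outer layer), and post-processing of vessel-wall
    circumferential and shear stresses, bubble volume, centroid displacement,
    asymmetric ratio and microstreaming fields, together with batch drivers
    for bubble-offset and vessel-size parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: no
RoxygenNote: 7.3.3
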