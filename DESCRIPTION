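Package: hemoflow
Title: Desk-Scale Haemodynamic Post-Processing for Aortic Flow Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reduced-order tools for cardiovascular haemodynamics: patient
    half-sine inlet waveforms, Carreau-Yasuda blood rheology, three-element
    Windkessel outlet models with automated tuning to systolic/diastolic
    pressure targets, wall-shear-stress indices (TAWSS, OSI, HOLMES),
    swirling-strength vortex identification on sampling planes, outlet
    flow-split analysis, and point-wise wall mechanics (Von Mises stress,
    two-parameter Mooney-Rivlin response). Ships analytic synthetic field
    generators (Womersley pulsatile pipe flow, rigid-body vortices,
    mass-conserving branching networks) with known ground truth, so every
    post-processing stage can be validated end to end without a 3D solver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, tools, yaml, xml2
Suggests: testthat (>= 3.0.0), deSolve, jsonlite, withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
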