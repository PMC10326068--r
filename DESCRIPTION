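Package: barbedend
Title: Kinetics of Formin, Capping Protein and Twinfilin at Actin Filament Barbed Ends
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic state model and inference tools for multicomponent
    regulation of actin filament barbed ends by formin, capping protein (CP)
    and twinfilin. Provides the closed-form occupancy solutions of the
    two-route decision-complex (BFC) dissociation model, an exact Gillespie
    simulator of per-filament barbed-end state trajectories with a
    TIRF-like observation layer (frame sampling, Gaussian noise,
    photobleaching), censored single-exponential survival fitting with
    two-route rate decomposition and parametric-bootstrap confidence
    intervals, and single-molecule dwell-time and visit-count statistics
    including per-visit uncapping probability estimation and photobleaching
    step counting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
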