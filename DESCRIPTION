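Package: circpol
Title: Multiplexed Circular Polarimetry for Label-Free Tissue Pathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for circular-polarimetry screening
    of fibrous tissue. Implements polarized Monte Carlo photon transport through
    slabs of axon-like cylindrical scatterers (infinite-cylinder and Mie series),
    a rotating quarter-wave-plate Stokes polarimeter forward model with Fourier
    demodulation, depolarization and Poincare-sphere retardance metrics,
    four-channel statistical-moment texture features, and a linear-SVM/ROC
    classification stage, together with a seeded synthetic scan-data generator
    that emulates zig-zag scans over ischemic and normal brain hemispheres.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
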