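Package: spinekin
Title: Cervical Spine Kinematics from Rigid Surface-Model Registration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures in vivo intervertebral kinematics of the cervical spine
    from per-vertebra triangle-mesh surface models. Provides STL/PLY mesh
    input and output, signed point-to-surface deviation statistics for
    model-accuracy validation, rigid 3D-3D registration by the iterative
    closest point method, anatomic coordinate frames built from bony
    landmarks, six-degree-of-freedom intervertebral translations and
    rotations with clinical sign conventions, and a synthetic vertebra
    generator at typical cervical dimensions so the full pipeline can be
    exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
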