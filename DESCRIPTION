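Package: rdiconn
Title: Voxel-Wise Head-Motion Artifacts in Resting-State Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies the spatially varying component of in-scanner head
    motion in resting-state fMRI and corrects its effect on population-level
    functional connectivity comparisons. Converts per-frame rigid-body
    realignment transforms into voxel-wise displacement fields and derives
    frame-wise (FD), regional (RD) and differential regional (deltaRD)
    displacement, computes DVARS-family BOLD change metrics, applies the
    standard first-level nuisance-regression strategies and band-pass
    filtering to regional time courses, builds Fisher-Z connectivity
    matrices, and fits edge-wise second-level GLMs with the Regional
    Displacement Interaction (RDI) covariate set. Includes a synthetic-cohort
    generator with controllable rigid-motion phenotypes and
    displacement-coupled BOLD artifacts so the full pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
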