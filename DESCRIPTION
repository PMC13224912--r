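Package: dualphasepet
Title: Dual-Phase Dynamic SV2A PET Simulation and Asymmetry Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for dual-phase dynamic brain PET
    with a synaptic-density tracer alongside static FDG. Provides a synthetic
    cohort generator (one-tissue-compartment kinetics on a left-right
    symmetric digital phantom, pharmacologic target blockade, unilateral
    lesions, PSF blurring, frame-duration-scaled noise), frame-schedule and
    SUV/SUVR arithmetic, regional time-activity-curve extraction and group
    comparison, framewise cross-tracer correlation with imaging-window
    selection, mirrored-subtraction hemispheric asymmetry mapping with
    Gaussian smoothing optimisation and lesion severity/volume metrics,
    Logan graphical kinetic analysis (VT, DVR), and a reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
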