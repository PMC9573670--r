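Package: gelshot
Title: Linac Isocenter QA from Polymer-Gel Dosimeter CBCT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fast linac irradiation-isocenter determination from
    kilovoltage CBCT/iCBCT readouts of 3D polymer-gel dosimeters. Provides
    CT volume I/O (single-frame DICOM series and NIfTI), a synthetic
    gel-phantom simulator with known ground truth (beam tracks, fiducial
    markers, mode-specific noise, beam-hardening and ring artifacts),
    series averaging, background subtraction and a filter bank, VOI noise
    and Catphan-style image-uniformity QA metrics with a tube-heating-aware
    scan scheduler, sinogram-based 2D star-shot and guided 3D beam-track
    detection, minimal-circle/sphere (Chebyshev) isocenter fitting with a
    fiducial-referenced offset, and configuration-driven end-to-end
    pipelines with machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    RNifti,
    signal,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
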