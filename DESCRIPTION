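Package: phantomqc
Title: Automated Phantom-Based Quality Control for Digital Radiography and
    Mammography
Version: 0.1.0
Authors@R: person("QC", "Maintainer", email = "qc@example.org",
    role = c("aut", "cre"))
Description: Analyzes images of simple copper/aluminium test phantoms for
    remote, automated quality control of radiographic and mammographic
    systems. Locates the slanted copper edge target, the low-contrast
    aluminium square and homogeneous noise regions automatically, and
    computes signal-difference-to-noise ratio (SDNR), large-area SNR,
    presampled directional MTF from the slanted edge, detrended normalized
    noise power spectra (NNPS), the non-prewhitening-with-eye-filter (NPWE)
    detectability index d', and a normalized local-variance map for artifact
    detection.  Tracks every exported metric over time with control charts
    (10%/15%/2-SD limit policies, monotone-run and moving-average trend
    rules).  Includes a synthetic phantom-image simulator with analytic
    ground truth so the full pipeline is testable without an X-ray device,
    plus minimal DICOM and 16-bit TIFF readers/writers and a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
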