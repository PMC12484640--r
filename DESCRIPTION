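Package: puncta
Title: Quantification of Biomolecular Condensate Imaging and Screening Readouts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify common readouts in biomolecular condensate
    biology: a two-channel enrichment statistic for LacO/LacI tethering
    assays (radial intensity profiling, punctum radius estimation from the
    profile derivative, box-filter smoothing and the Ipeak/Iperiphery
    ratio), droplet segmentation with per-droplet morphometrics, line
    profiles and object-based co-condensation efficiency, normalization
    and single-exponential fitting of fluorescence recovery after
    photobleaching (FRAP) traces, and count normalization, log2 fold
    change and candidate classification for pooled CRISPR screens.
    Includes seeded synthetic-data generators with known ground truth for
    every readout, plus TIFF/CSV readers and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
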