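Package: nmjquant
Title: Headless Quantification of Exosome Release and Autophagosome
    Puncta at the Drosophila Neuromuscular Junction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reproducible, scriptable reimplementation of two interactive
    ImageJ workflows used at the Drosophila larval neuromuscular junction:
    quantification of extrasynaptic fluorescence (exosome release) in a
    calibrated shell around an Otsu-segmented synaptic bouton, and
    detection, size/circularity filtering, centroid-distance merging and
    counting of fluorescent protein clusters (autophagosomes) inside a
    segmented region. Includes a synthetic two-channel image generator
    with exhaustive ground truth, TIFF ingestion with micrometer
    calibration, CSV/JSON emission, a batch driver and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
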