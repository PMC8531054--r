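Package: quicsr
Title: Image Quality Metrics for Fluorescence Microscopy via Image Correlation Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores single-channel (super-resolution) fluorescence microscopy
    images with three quantities extracted from the radial spatial
    autocorrelation function of one image: an effective Resolution (nm), a
    molecular Brightness (counts), and a relative noise variance. The
    noise-free correlation amplitude is estimated either by skipping the
    zero-lag point in a Gaussian fit or by cross-correlating two
    noise-independent images obtained by checkerboard downsampling. Includes
    a ground-truth-annotated synthetic image generator (point or finite-size
    Gaussian particles convolved with a Gaussian point spread function, plus
    uniform background, Poisson/Gaussian noise and photobleaching series),
    TIFF input with region-of-interest masks, batch analysis, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    tiff,
    png,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
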