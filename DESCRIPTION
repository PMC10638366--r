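Package: poremorph
Title: Automated Pore-Pattern Morphometrics of Bolivinid Foraminifera and
    Bottom-Water Nitrate Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures pore patterns on scanning electron microscope (SEM)
    images of bolivinid foraminifera tests: specimen detection, per-pore
    segmentation by a classical operator chain or a trainable
    pixel-classification segmenter, ontogenetic size-normalization to the
    oldest chambers covering 50,000-70,000 square micrometers, and
    extraction of pore density, mean pore size and porosity. Includes the
    statistical toolkit used for pore-pattern analyses (ordinary
    least-squares regression, Student's and Welch's t tests, Wilcoxon
    rank-sum with exact small-sample enumeration, Shapiro-Wilk), the
    pore-density to bottom-water-nitrate transfer function with
    species-applicability guards and environmental covariate screening,
    and a synthetic SEM-image generator with exact ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    nnet,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
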