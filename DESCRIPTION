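Package: tfLC3quant
Title: Hue-Angle Quantification of Tandem-Fluorescent LC3 Autophagy Reporter Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Neuron-level quantification of autophagic-lysosomal vesicle
    subtypes from triple-fluorescent confocal images of the tandem
    mRFP-eGFP-LC3 (tfLC3) reporter plus a cathepsin-D immunolabel.
    Puncta are segmented by perikaryon-derived channel thresholds,
    watershed splitting of clumped vesicles and size exclusion; each
    vesicle's mean RGB intensities are converted to a hue angle and
    saturation and classified as autophagosome (yellow), autolysosome
    (purple), poorly acidified autolysosome (white) or lysosome (blue),
    yielding per-neuron subtype counts. Additional tools partition a
    fourth immunoreactivity channel into autophagic-vacuole-associated
    and unassociated areas, compute integrated densities with
    low-staining region exclusion, and run the group statistics used
    for such data (unpaired t-tests, one-way ANOVA with Sidak-adjusted
    selected comparisons). A synthetic confocal scene simulator with
    per-vesicle ground truth makes the whole pipeline testable without
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    withr,
    optparse
biocViews: Software, CellBiology, Visualization, Classification
Config/testthat/edition: 3
RoxygenNote: 7.3.3
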