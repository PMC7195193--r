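Package: wormExM
Title: Quantitative Image Analysis for Expansion Microscopy of C. elegans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for whole-animal expansion microscopy of
    C. elegans: expansion-isotropy analysis (rigid scaled-rotation plus
    non-rigid registration of pre/post-expansion image pairs and the
    root-mean-square length-measurement-error curve), prominence-filtered
    counting of synaptic puncta along line-intensity profiles, 3D FISH-HCR
    spot calling with per-neuron counts, percentile-mask signal-to-background
    ratios for immunostaining, and worm/hydrogel expansion-factor metrics
    including the normalized expansion factor. A parametric worm-phantom
    generator provides ground truth (deformation fields, puncta and transcript
    coordinates, per-cell counts, masks) for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
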