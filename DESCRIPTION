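Package: tandemflux
Title: Autophagic Flux Quantification from Tandem mCherry-EGFP-LC3B Reporter
    Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies autophagic flux from tandem mCherry-EGFP-LC3B
    fluorescence microscopy: counts DAPI-stained nuclei, detects red and
    green fluorescent LC3 vesicles, classifies them into autophagosomes
    (red and green) and autolysosomes (red only, EGFP quenched) by
    object-based colocalization, normalizes counts per cell, and applies
    ANOVA/Tukey group statistics with a drug-versus-bafilomycin decision
    rule to call flux induction or blockade. Also provides 2^-ddCt
    relative expression quantification with dual reference genes,
    RECIST-adapted response classification of zebrafish xenograft tumor
    volumes with waterfall summaries, and a synthetic-data generator
    (reporter image fields with ground truth, Ct tables, xenograft
    cohorts) so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
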