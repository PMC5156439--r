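Package: robustsig
Title: Transcriptome Signatures of Stress Robustness in Lactococcus lactis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Transcriptome-phenotype matching pipeline for identifying gene
    expression signatures of stress robustness in Lactococcus lactis
    fermentations. Computes CFU-based heat and oxidative stress survival
    phenotypes (log10 reduction), preprocesses two-color microarray
    intensities (MA transformation, lowess dye-bias normalization,
    loop-design unfolding, probe-to-ORF median aggregation), fits per-gene
    linear models of 2-log expression against robustness across fermentation
    conditions, selects per-strain signatures by dual-timepoint significance
    and P-value products, and ranks cross-strain generic signatures over
    orthologous groups. Includes a seeded synthetic-data generator emulating
    the full factorial fermentation design so every stage is testable
    without external array data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
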