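Package: mrmati
Title: Targeted LC-MS/MS Method Design and Relative Quantification of
    Cereal Alpha-Amylase/Trypsin Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating targeted proteomics (multiple
    reaction monitoring, MRM) assays for cereal alpha-amylase/trypsin
    inhibitors (ATIs) and similar small seed proteins.  Covers in-silico
    tryptic digestion with missed-cleavage and length control, monoisotopic
    precursor and y/b fragment m/z computation with fixed modifications,
    proteotypic (quantifier/qualifier) peptide selection against a background
    proteome, Skyline-style transition-list import/export, protein-level
    descriptors (average molecular weight, isoelectric point), global pairwise
    sequence alignment statistics, internal-standard normalisation of peak-area
    tables, relative quantification per mg flour with composition percentages,
    ICH-style method validation (linearity, LOD/LOQ from the intercept standard
    deviation, recovery, %RSD), and a synthetic MRM data generator with known
    ground truth for method verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
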