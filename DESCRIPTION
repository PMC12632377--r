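Package: olscape
Title: Organelle Proteome Landscape Analysis for Multi-Genotype Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for organelle-resolved differential proteomics
    across panels of knockout cell lines: per-protein fold-change contrasts with
    Benjamini-Hochberg correction, annotation-restricted fold-change correlation
    landscapes, a composite organelle correlation map with disease-class
    summaries and ranked organelle impact scores, lysosome immunopurification
    (LysoIP) co-enrichment statistics with rank-sum organelle shift tests, and
    ratio-of-ratios spatial proteomics for soma/projection fractionation
    designs. Includes a synthetic multi-genotype proteome generator with
    planted annotation-level effects for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
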