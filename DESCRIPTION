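Package: tandemCNV
Title: Digital Genotyping of Multicopy Genes and Macrosatellite Repeats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multiplexed digital count assays targeting
    multicopy genes and large tandem repeats. Implements background
    correction against negative-control probes, invariant-probe
    normalization, calibration of relative counts to absolute diploid copy
    number using read-depth anchors, copy-number variability classification,
    ANOVA-based V_ST population differentiation, tag-SNP linkage
    disequilibrium scanning with permutation testing, cis expression and
    CpG-methylation association with staged filters and permutation nulls,
    comparative primate copy-number analysis with identity-based retention,
    dN/dS distribution comparison, and a synthetic-data generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
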