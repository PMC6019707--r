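Package: HLAtrio
Title: Pedigree-Based Evaluation of HLA Typing Methods
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Gold-standard-free evaluation of computational HLA class I
    typing using family trios. Parses and reduces HLA allele identifiers
    across resolution levels and tool output dialects, measures Mendelian
    trio consistency (Descent Accuracy), cross-method agreement (Method
    Agreement, with transmitted/non-transmitted splits), and population
    statistics (homozygosity rates, direct-counting allele frequencies,
    top-k ranking against reference populations, common/well-documented
    classification). Includes a synthetic trio-cohort simulator with
    Hardy-Weinberg founders, Mendelian transmission and configurable typer
    error models (random and serotype-preserving miscalls, homozygote
    inflation, resolution truncation) so every statistic is verifiable
    without access to a restricted cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
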