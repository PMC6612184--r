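Package: skintraits
Title: Trait-Based Comparison of Skin and Reference Bacterial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for trait-based analysis of culture-derived bacterial
    trait databases, built around the human skin microbiome. Provides a
    schema-driven data model for binary, categorical and quantitative
    traits with explicit unknown values; abundance-threshold screening of
    taxa from taxonomic classification reports; binomial-proportion,
    chi-square and randomization tests for binary and categorical traits;
    nonparametric relative-effect (Brunner-Munzel) comparisons with
    Tukey-type all-pairs multiplicity adjustment for quantitative traits;
    naive and phylogenetically corrected logistic regressions of group
    membership on single traits with likelihood-ratio screening; and a
    synthetic-data generator with known ground truth for calibrating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    mvtnorm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
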