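Package: irproteo
Title: Tissue-Specific Insulin Resistance and the Plasma Proteome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links muscle- and liver-specific insulin resistance, quantified
    from five-point oral glucose tolerance test (OGTT) curves via the muscle
    insulin sensitivity index (MISI) and the hepatic insulin resistance index
    (HIRI), to plasma proteome abundance profiles. Provides mutually adjusted
    per-protein linear models with empirical-Bayes variance moderation,
    Benjamini-Hochberg false discovery rate control, hypergeometric pathway
    overrepresentation analysis with many-to-many aptamer-to-gene mapping, and
    a synthetic cohort generator with planted effects so the whole pipeline is
    testable without access to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse
Config/testthat/edition: 3
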