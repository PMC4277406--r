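Package: tissuespec
Title: Tissue-Specificity Classification of Bulk RNA-seq Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies genes into seven tissue-specificity categories
    (not detected, highly and moderately tissue enriched, group enriched,
    enhanced, expressed in all, mixed) from replicate-averaged FPKM
    profiles across a panel of tissues, using fold-change rules relative
    to a detection cutoff of 1 FPKM. Includes replicate and inter-tissue
    Spearman correlation, average-linkage clustering with Newick export,
    differential-detection gene sets, a bipartite tissue/enriched-set
    network with SIF and GraphML export, per-category count and
    transcript-fraction summaries, and a synthetic FPKM generator with
    planted category structure, multiplicative replicate noise and
    barcode-leakage mixing for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
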