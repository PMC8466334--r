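Package: scentmark
Title: Source Attribution and Individual Discrimination of Solitary-Bee Nest Scent Marks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for GC/MS peak-area tables of solitary-bee nest
    scent marks and their candidate glandular and cuticular sources. Provides
    substance filtering against control sleeves, private-substance screening,
    quantile normalization, centered log-ratio transformation, attribution of
    mark compounds to Dufour's gland, head/cuticle, or exogenous origin via a
    Kovats-index regression band and enrichment filters, estimation of
    per-individual total bouquets, PCA-based squared-Euclidean-distance
    similarity analysis with a binomial-logit Wald test of same-nest versus
    different-nest similarity, UPGMA-clustered heatmaps with sorted
    dendrograms, and a synthetic multi-source peak-table generator with ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
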