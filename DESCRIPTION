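Package: multifunr
Title: Genome-Wide Detection of Multifunctional Genes from Ontology Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects multifunctional genes from Gene Ontology style
    annotation data by selecting terms of comparable specificity,
    filtering term pairs for structural and co-annotation distinctness
    (root-only common ancestry, no shared descendants, hypergeometric
    co-annotation test), and taking the union of calls over a grid of
    specificity levels. Includes group-comparison statistics
    (Mann-Whitney, hypergeometric enrichment, partial Spearman,
    covariate-matched resampling, bootstrap median intervals), protein
    interaction network centralities (degree, betweenness,
    participation coefficient) with iterative hub pruning, a
    cross-species conservation-of-multifunctionality permutation test,
    per-gene feature derivation, and seeded synthetic-data generators
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
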