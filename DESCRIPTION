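Package: phosphoDiff
Title: Differential Phosphorylation and Multi-Omics Concordance Analysis
    for Label-Free Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for paired total-proteome, phosphopeptide and
    transcriptome experiments with a common sample design. Implements
    protein-level normalization of phosphopeptide abundances, two
    complementary strategies for calling differentially phosphorylated
    peptides (a normalized-difference statistic screened with the
    Iglewicz-Hoaglin modified Z-score, and an all-pairs ratio test with
    Bonferroni control), robust proteome-transcriptome fold-change
    concordance, metagene gain-/loss-of-function classification of shared
    differentially expressed genes, hypergeometric overrepresentation
    analysis with bubble-plot term selection, binary transcription
    factor-target matrix clustering, and protein-protein interaction hub
    ranking. A synthetic-data generator with planted ground truth makes the
    whole pipeline testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    limma,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
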