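Package: stressnet
Title: Co-Expression Network Analysis of Dual Abiotic Stress Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for microarray-style transcriptome responses to
    aluminium toxicity and phosphate starvation in poplar roots. Identifies
    differentially expressed genes by Student's t-test with present/absent
    filtering, computes stress/control regulation coefficients with 20% and
    two-fold categorical filters, builds signed Spearman co-expression networks
    with a t-distribution significance test, summarizes network topology
    (degrees, hubs, ego networks, library similarity maps), and classifies
    cross-stress concordance and regulation-sign gene groups. Includes a
    synthetic-data generator with planted differential expression and
    correlated gene modules for validation, plus parsers for tabular BLAST
    output and curated reference gene lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
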