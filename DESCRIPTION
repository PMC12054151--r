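Package: oralmpg
Title: Metapangenomic Coverage, Habitat-Preference and Enrichment Analysis
    for Oral Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for coverage-based analysis of bacterial genome
    distributions across human oral habitats from shotgun-metagenome read
    recruitment. Implements breadth-of-coverage genome and gene detection,
    interquartile-mean (Q2Q3) depth summaries and relative abundances, an
    exhaustive binary site-partition classifier of habitat preference
    scored by Student's t and Rao score statistics, reference-genome
    quality filtering and ANI-based dereplication, KEGG-style module
    completeness and habitat-group functional enrichment with
    Benjamini-Hochberg control, sub-group detection via Ward clustering
    with gap-statistic model selection, and a site-structured coverage
    simulator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
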