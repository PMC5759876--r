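Package: pangtm
Title: Bacterial Pan-Genome Analysis and Gene-Trait Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative pan-genomics toolkit for sets of closely related
    bacterial genomes: Markov clustering of all-vs-all protein similarities
    into gene families, core/dispensable/unique partitioning, pan- and
    core-genome accumulation curves with fitted Heaps-law and exponential
    decay models, neighbor-joining core-gene supertrees with majority-rule
    consensus, OD600 growth-curve binarization, and gene-trait matching of
    gene-family occurrence patterns against binary carbohydrate-utilization
    phenotypes. Includes a synthetic pan-genome simulator with planted
    carbohydrate-utilization gene clusters for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
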