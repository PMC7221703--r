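Package: herbnet
Title: Layered Network Pharmacology for Herbal Component-Target-Pathway Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Systems-biology inference chain for herbal network pharmacology
    on layered herb-component-target-pathway-phenotype knowledge graphs:
    random-walk-with-restart phenotype association with a closed-form oracle,
    component-target-bioprocess route enumeration with a path-frequency
    score, one-sided Fisher (hypergeometric) pathway enrichment with a
    sort/deduplicate consolidation step, and layered-network comparison with
    degree ranking. Ships the printed red-ginseng component-target-pathway
    data as a built-in fixture and a seeded synthetic knowledge-graph
    generator with planted enrichment and phenotype signals for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'knowledge-graph.R'
    'gene-sets.R'
    'fixture.R'
    'generator.R'
    'rwr.R'
    'path-explorer.R'
    'enrichment.R'
    'network-compare.R'
    'pipeline.R'
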