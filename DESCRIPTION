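Package: proxitax
Title: Phylogeny-Based Taxonomic Assignment of Prokaryotic Marker Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating nomenclature-aware prokaryotic reference
    databases (type-strain tagging, stringency flavors, missing-type-strain
    quality control) and for assigning query sequences to species and genera
    from phylogenetic trees built over BLAST-recruited neighbors. The
    assignment engine works on patristic distances: it reports the closest
    reference leaf, the proximal cluster of leaves within a small topological
    distance of the query, percentile-based species and genus suggestions
    derived from intra-species and intra-genus distance distributions, and a
    set of diagnostic warnings. Includes Newick input/output with support
    labels, midpoint rooting, taxonomy-relabelled trees, a pipeline
    orchestrator with pluggable alignment/inference backends, and a synthetic
    fixture generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    phangorn,
    phytools,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
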