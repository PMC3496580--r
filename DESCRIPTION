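Package: pipegraph
Title: Graph-Based Composition of Extensible Format-Conversion Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compiles a tabular registry of command-line tools into a directed
    multigraph in which data formats are nodes and tools are weighted edges,
    then composes executable, function-specific pipelines between any two
    formats with a shortest-path search (performance or input-dependency
    weighting, deterministic tie-breaking, parallel edges). Compiled pipelines
    are materialised as .inputs/.exec/.outputs manifests and can be executed
    locally with error capture. Connectivity analytics report the number of
    possible conversions a registry offers and the gain from registering a new
    tool. A bundled suite of diploid population-genetics converters
    (PolyPhred genotypes, PrettyBase, SDAT, Structure, PHASE, NEXUS, FASTA,
    hierfstat tables) makes composed pipelines runnable end to end, and a
    synthetic-data module generates genotype datasets and random registries
    for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    optparse,
    seqinr,
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
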