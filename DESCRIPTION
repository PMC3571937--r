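Package: syntenymap
Title: Prokaryotic Synteny Maps from Translated Protein Searches
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks annotated prokaryotic genomes against a query protein by
    normalized six-frame translated-search scores, extracts fixed-width
    genomic windows centered on the best hits, colors orthologs and paralogs
    by Smith-Waterman-Gotoh connected components in a star topology around
    the top-ranked genome, and renders scale-exact gene maps (SVG, PDF, CSV)
    that make gene fusions visible by eye. Includes a 7-rank taxonomy tree
    for lineage-driven genome selection, a multi-query gene-cluster scanner
    based on bounded inter-hit distances, a GenBank flat-file reader/writer,
    and a seeded generator of synthetic annotated genomes with planted
    ortholog clusters for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    grid,
    grDevices,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
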