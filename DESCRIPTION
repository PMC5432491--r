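Package: pedscan
Title: Genome-Wide Pedigree Dissection for Inbred Crop Cultivars
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the breeding history of inbred crop
    cultivars from dense SNP genotypes and a documented pedigree.
    Detects identity-by-descent (IBD) haplotype blocks between pairs of
    homozygous lines with a deterministic concordance-run detector,
    classifies ancestor-to-descendant transfer paths as direct or
    indirect over the pedigree graph, aggregates per-pair IBD totals,
    runs sliding-window selection scans (Tajima's D, Nei's gene
    diversity, polymorphism information content) with a four-quadrant
    selection-timing classifier, fits linkage-disequilibrium decay to
    call favorable gene clusters, and intersects QTL intervals with IBD
    blocks to nominate candidate genes.  A forward simulator of breeding
    pedigrees with exact founder-origin tracking provides ground truth
    for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    IRanges,
    S4Vectors,
    vcfR,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
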