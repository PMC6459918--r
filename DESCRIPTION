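Package: thioscape
Title: Phosphorothioate Modification Landscapes and Defence-System
    Neighbourhood Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing DNA phosphorothioate (PT) modification
    landscapes in prokaryotic genomes and the gene neighbourhoods of
    PT-based defence systems.  Scans genomes for palindromic GATC duplex
    loci, classifies strand-resolved PT calls into hemi- and fully
    modified duplex states, and summarises modification density, spacing
    and flanking-base context bias.  Mines filtered protein homology hits
    for dndCD modification loci, searches flanking windows for
    restriction (dndFGH) and exclusion (pbeABCD) partners, and classifies
    genomes into co-occurrence categories.  Implements needle-style
    affine-gap global protein alignment with identity and similarity
    percentages, per-strain similarity-rate tables against fixed
    references, a coevolution regression and correlation fit,
    alignment-distance matrices with neighbour-joining trees, and the
    scalar plaque-assay and qPCR formulas used in virus-defence assays.
    A seeded synthetic-data generator produces genomes with planted
    motifs, PT call sets of chosen composition, annotation tables with
    planted defence-gene clusters, and correlated protein-family pairs,
    so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
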