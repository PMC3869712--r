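Package: barcodetools
Title: DNA Barcode Species Identification and Species-Boundary Delimitation
Version: 0.1.0
Authors@R:
    person("Barcode", "Tools Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing aligned COI barcode libraries: Kimura
    2-parameter distances with pairwise deletion, intraspecific/interspecific
    distance partitioning and barcode-gap analysis, leave-one-out species
    identification under the best match (BM), best close match (BCM) and all
    species barcodes (ASB) protocols with threshold sweeps and ad hoc
    threshold estimation by linear regression, a back-propagation neural
    network classifier, minimum-spanning haplotype networks with mutational
    step counts, neighbor-joining trees with nonparametric bootstrap and
    monophyly assessment, and a seeded simulator of barcode libraries with
    known ground truth (including taxonomic oversplitting scenarios).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
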