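Package: lineageAffinity
Title: Environmental Affinity and Evolutionary Relatedness of Sedimentary
    DNA Lineages
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for testing whether the evolutionary relatedness of
    closely related diatom lineages recovered from lake sedimentary DNA
    tracks environment rather than geography. Covers clone dereplication
    and authenticity filtering, uncorrected nucleotide and patristic
    distances, minimum-spanning haplotype networks with inferred
    intermediate haplotypes, per-lineage transect / vegetation-type /
    Larix-pollen affinities, and a constrained-ordination engine
    (Bray-Curtis, NMDS with Kruskal stress-1, RDA, PCoA, distance-based
    RDA) with permutation tests and forward selection. A synthetic
    sedimentary-DNA generator (Yule trees, Jukes-Cantor sequence
    evolution, Gaussian niche occupancy over a tundra-taiga gradient,
    clone libraries with polymerase errors) makes the whole pipeline
    testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    vegan,
    igraph,
    jsonlite
Config/testthat/edition: 3
biocViews: Phylogenetics, Metagenomics, SequenceMatching, Clustering
RoxygenNote: 7.3.3
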