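Package: chromoPhylo
Title: Rooted Chromosomal Phylogenies from Fixed Paracentric Inversions
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring rooted chromosomal phylogenies of sibling
    species complexes from fixed paracentric inversions, modelled on the
    Anopheles gambiae complex. Karyotypes of arrangement states are encoded
    as signed permutations per chromosome arm under an overlapping-inversion
    trajectory constraint; reversal distances are computed by the
    Hannenhalli-Pevzner breakpoint-graph formula with an exhaustive
    breadth-first oracle; minimum-event trees are reconstructed under
    alternative outgroup arrangement ancestries with per-inversion origin
    counts. Inversion breakpoints are detected from same-orientation
    discordant mate pairs, arrangement states are called from
    breakpoint-flanking gene adjacencies in outgroup genomes, and miniature
    inverted-repeat transposable element (MITE) boundaries and target-site
    duplication lengths are defined from repeat copies with flanking
    alignment. A seeded synthetic-data generator produces genomes, karyotype
    histories on trees, mate-pair libraries and MITE insertions with
    machine-readable truth records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ape,
    phangorn,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
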