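test_that("ancestral genome simulation is seeded and respects gene capacity", {
  g1 <- simulateAncestralGenome(20000, nGenes = 30, seed = 1)
  g2 <- simulateAncestralGenome(20000, nGenes = 30, seed = 1)
  expect_equal(as.character(g1$genome), as.character(g2$genome))
  expect_equal(length(g1$genes), 30L)
  expect_true(all(GenomicRanges::width(g1$genes) == 500L))
  ol <- GenomicRanges::findOverlaps(g1$genes, drop.self = TRUE,
                                    ignore.strand = TRUE)
  expect_length(ol, 0L)
  expect_error(simulateAncestralGenome(1000, nGenes = 100, seed = 1),
               "cannot fit")
})

test_that("mate-pair simulation honours the coverage formula and insert law", {
  g <- simulateAncestralGenome(50000, nGenes = 0, seed = 2)$genome
  lib <- librarySpec(2000, insertSd = 200)
  mp <- simulateMatePairLibrary(g, lib, coverage = 10, seed = 3)
  expect_equal(length(mp$read1), as.integer(ceiling(10 * 50000 / (2 * 36))))
  expect_equal(length(mp$read1), length(mp$read2))
  expect_equal(unique(Biostrings::width(mp$read1)), 36L)
  # zero coverage, zero pairs
  mp0 <- simulateMatePairLibrary(g, lib, coverage = 0, seed = 3)
  expect_length(mp0$read1, 0L)
  # mean insert within 1% of specification at large pair counts
  big <- simulateMatePairLibrary(g, lib, coverage = 150, seed = 4)
  expect_lt(abs(mean(big$truth$insert) - 2000) / 2000, 0.01)
  # read pairs are genuine FR fragments of the genome
  i <- 17L
  frag <- subseq(g, mp$truth$start0[i] + 1,
                 mp$truth$start0[i] + mp$truth$insert[i])
  expect_equal(as.character(mp$read1[[i]]), as.character(subseq(frag, 1, 36)))
  expect_equal(as.character(mp$read2[[i]]),
               as.character(reverseComplement(subseq(frag, length(frag) - 35,
                                                     length(frag)))))
})

test_that("MITE planting duplicates target sites and grows the genome exactly", {
  g <- simulateAncestralGenome(60000, nGenes = 0, seed = 5)$genome
  pm <- plantMite(g, elementLength = 200, tsdLength = 3, copies = 10, seed = 6)
  expect_equal(length(pm$genome) - length(g), 10L * (200L + 3L))
  tr <- pm$truth
  for (i in seq_along(tr)) {
    s <- GenomicRanges::start(tr)[i]; e <- GenomicRanges::end(tr)[i]
    up <- as.character(subseq(pm$genome, s - 3, s - 1))
    dn <- as.character(subseq(pm$genome, e + 1, e + 3))
    expect_equal(up, dn)   # identical 3-mers flank every copy
  }
  pm0 <- plantMite(g, elementLength = 200, tsdLength = 0, copies = 3, seed = 7)
  expect_equal(length(pm0$genome) - length(g), 3L * 200L)
  expect_error(plantMite(DNAString("ACGT"), elementLength = 350, seed = 1),
               "longer than genome")
})

test_that("karyotype evolution on the complex's event set is distance-consistent", {
  catalog <- gambiaeComplexCatalog()
  rc <- realizeCatalog(catalog, armLength = 40000L, seed = 8)
  taxa <- c("gambiae", "merus", "arabiensis", "quadriannulatusA",
            "quadriannulatusB", "bwambae", "melas", "outgroup")
  tree <- ape::read.tree(text = paste0(
    "(outgroup,(merus,(gambiae,(arabiensis,((quadriannulatusA,",
    "quadriannulatusB),(bwambae,melas))))));"))
  tree <- ape::reorder.phylo(tree, "cladewise")
  # root carries the ancestral karyotype: Xag, 2Ro, 2La
  rootStates <- setNames(rep("standard", 10), catalogInversions(catalog)$name)
  rootStates[c("Xa", "Xg", "2Ro", "2La")] <- "inverted"
  ev <- vector("list", nrow(tree$edge))
  tipOf <- function(lab) match(lab, tree$tip.label)
  edgeTo <- function(node) which(tree$edge[, 2L] == node)
  ev[[edgeTo(tipOf("merus"))]] <- "2Rp"
  ev[[edgeTo(tipOf("melas"))]] <- "2Rm"
  ev[[edgeTo(tipOf("arabiensis"))]] <- c("Xb", "Xc", "Xd")
  # internal edges, located by clade membership
  desc <- function(node) if (node <= 8) tree$tip.label[node] else
    unlist(lapply(tree$edge[tree$edge[, 1L] == node, 2L], desc))
  for (i in seq_len(nrow(tree$edge))) {
    d <- sort(desc(tree$edge[i, 2L]))
    if (identical(d, sort(c("gambiae", "arabiensis", "quadriannulatusA",
                            "quadriannulatusB", "bwambae", "melas"))))
      ev[[i]] <- "2Ro"          # gambiae lineage reverts o to standard
    if (identical(d, sort(c("arabiensis", "quadriannulatusA",
                            "quadriannulatusB", "bwambae", "melas"))))
      ev[[i]] <- c("Xa", "Xg")  # loss of Xag
    if (identical(d, sort(c("quadriannulatusA", "quadriannulatusB",
                            "bwambae", "melas"))))
      ev[[i]] <- "2La"          # 2L+a fixation
    if (identical(d, sort(c("bwambae", "melas"))))
      ev[[i]] <- "3La"
  }
  evo <- evolveKaryotypes(rc, tree, ev, catalog, rootStates = rootStates)
  expect_equal(sort(names(evo$genomes)), sort(taxa))
  # 8 distinct genomes except the quadriannulatus pair
  keyOf <- function(tx) paste(vapply(evo$genomes[[tx]], as.character, ""),
                              collapse = "|")
  keys <- vapply(taxa, keyOf, "")
  expect_equal(keys[["quadriannulatusA"]], keys[["quadriannulatusB"]])
  expect_equal(length(unique(keys)), 7L)
  # truth karyotypes equal the complex's published arrangement states
  km <- gambiaeKaryotypeMatrix("Xag")
  expect_equal(evo$karyotypes@states[taxa, colnames(km@states)],
               km@states[taxa, ])
  # permutations recovered from the genomes equal the encoded truth, and
  # pairwise genome distances match the rearrangement engine
  for (tx in c("merus", "arabiensis", "melas")) {
    for (arm in catalogArms(catalog)) {
      rec <- recoverArmPermutation(evo$genomes[[tx]][[arm]], rc$segTags[[arm]])
      expect_equal(rec, evo$perms[[tx]][[arm]])
    }
  }
  dmTruth <- pairwiseDistanceMatrix(evo$karyotypes)
  dmEncoded <- pairwiseDistanceMatrix(km)
  expect_equal(dmTruth$total[taxa, taxa], dmEncoded$total[taxa, taxa])
  # empty event set leaves all genomes identical
  evo0 <- evolveKaryotypes(rc, tree, vector("list", nrow(tree$edge)), catalog)
  keys0 <- vapply(taxa, function(tx)
    paste(vapply(evo0$genomes[[tx]], as.character, ""), collapse = "|"), "")
  expect_equal(length(unique(keys0)), 1L)
  # an impossible event order is rejected
  evBad <- ev
  evBad[[edgeTo(tipOf("gambiae"))]] <- "2Rp"   # flip p on the merus background
  badTree <- tree
  expect_error(evolveKaryotypes(rc, tree,
    replace(vector("list", nrow(tree$edge)), edgeTo(tipOf("merus")),
            list(c("2Rp", "2Ro"))), catalog), NA)
})

test_that("seeded determinism holds end to end for the generators", {
  a <- simulateInversionGenome(30000, 9000, 21000, gapLength = 500, seed = 9)
  b <- simulateInversionGenome(30000, 9000, 21000, gapLength = 500, seed = 9)
  expect_equal(as.character(a$derived), as.character(b$derived))
  g <- a$reference
  lib <- librarySpec(2000, insertSd = 0)
  m1 <- simulateMatePairLibrary(g, lib, coverage = 2, seed = 10)
  m2 <- simulateMatePairLibrary(g, lib, coverage = 2, seed = 10)
  expect_equal(as.character(m1$read1), as.character(m2$read1))
  p1 <- plantMite(g, copies = 4L, seed = 11)
  p2 <- plantMite(g, copies = 4L, seed = 11)
  expect_equal(as.character(p1$genome), as.character(p2$genome))
})
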