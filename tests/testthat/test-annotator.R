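test_that("breakpoint-region arithmetic uses 1-based inclusive coordinates", {
  expect_equal(regionLength(9485167, 9486712), 1546)
  expect_equal(regionLength(29838366, 29839163), 798)
  expect_equal(regionLength(5, 5), 1)
  expect_error(regionLength(10, 9), "start")
  # coordinate-system round trip preserves lengths
  z <- coords1to0(9485167, 9486712)
  expect_equal(z$end0 - z$start0, 1546)
  back <- coords0to1(z$start0, z$end0)
  expect_equal(regionLength(back$start, back$end), 1546)
})

test_that("region size ratios are reported to one decimal", {
  expect_equal(compareRegionSizes(1546, 595), 2.6)
  expect_equal(compareRegionSizes(10, 5), 2.0)
  expect_equal(compareRegionSizes(7, 7), 1.0)
  expect_error(compareRegionSizes(0, 5), "positive")
})

test_that("arrangement states are inferred from junction adjacencies", {
  cat2 <- catalog2Rop()
  obs <- data.frame(
    species = c("stephensi", "stephensi", "gambiae", "gambiae", "culex"),
    geneA = c("AGAP001760", "AGAP001762", "AGAP001983", "AGAP003327",
              "AGAP003327"),
    geneB = c("AGAP002933", "AGAP002935", "AGAP001984", "AGAP003328",
              "AGAP003328"),
    sameScaffold = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  calls <- inferArrangementState(obs, cat2)
  pick <- function(sp, inv) calls$state[calls$species == sp & calls$inversion == inv]
  expect_equal(pick("stephensi", "2Ro"), "inverted")
  expect_equal(pick("gambiae", "2Rp"), "standard")
  # anchors on different scaffolds stay unresolved and are excluded from voting
  expect_equal(pick("culex", "2Rp"), "unresolved")
  v <- ancestryVote(calls)
  expect_equal(v$ancestral[v$inversion == "2Ro"], "inverted")
  expect_equal(v$nInverted[v$inversion == "2Rp"] +
               v$nStandard[v$inversion == "2Rp"], 1L)  # culex did not vote
  # contradictory adjacencies are flagged
  con <- data.frame(species = "x",
                    geneA = c("AGAP001760", "AGAP001760"),
                    geneB = c("AGAP002933", "AGAP001762"),
                    sameScaffold = TRUE, stringsAsFactors = FALSE)
  cc <- inferArrangementState(con, cat2)
  expect_true(any(cc$conflict[cc$inversion == "2Ro"]))
})

test_that("ortholog ids and anchor aliases resolve to catalog anchors", {
  full <- gambiaeComplexCatalog()
  orth <- data.frame(id = c("CPIJ004936", "CPIJ004938"),
                     anchor = c("AGAP007068", "AGAP005778"),
                     stringsAsFactors = FALSE)
  obs <- data.frame(species = "culex", geneA = "CPIJ004936",
                    geneB = "CPIJ004938", sameScaffold = TRUE,
                    stringsAsFactors = FALSE)
  calls <- inferArrangementState(obs, full, orthologs = orth)
  # Culex orthologs of AGAP007068/AGAP005778 lie adjacent: the inverted (2La)
  # arrangement is ancestral
  expect_equal(calls$state[calls$inversion == "2La"], "inverted")
  # AGAP013533 aliases the AGAP001983-side block of the distal 2Rp breakpoint
  obs2 <- data.frame(species = "y", geneA = "AGAP013533", geneB = "AGAP001984",
                     sameScaffold = TRUE, stringsAsFactors = FALSE)
  calls2 <- inferArrangementState(obs2, full)
  expect_equal(calls2$state[calls2$inversion == "2Rp"], "standard")
})

test_that("junction-model round trip recovers the generating state", {
  cat2 <- catalog2Rop()
  map <- buildSegmentMap(cat2, "2R")
  for (o in c("standard", "inverted")) for (p in c("standard", "inverted")) {
    perm <- encodeKaryotype(st2R(o, p), cat2)[["2R"]]
    ja <- junctionAdjacencies(perm, map)
    obs <- data.frame(species = "sp", geneA = ja$anchorLeft,
                      geneB = ja$anchorRight, sameScaffold = TRUE,
                      stringsAsFactors = FALSE)
    obs <- obs[!grepl(":", obs$geneA) & !grepl(":", obs$geneB), ]
    calls <- inferArrangementState(obs, cat2)
    expect_equal(calls$state[calls$inversion == "2Ro"], o)
    expect_equal(calls$state[calls$inversion == "2Rp"], p)
  }
})

test_that("repeat-copy search finds planted copies on both strands", {
  g0 <- simulateAncestralGenome(60000, nGenes = 0, seed = 2)$genome
  pm <- plantMite(g0, elementLength = 300, tsdLength = 0, copies = 6,
                  seed = 3, minSpacing = 3000)
  copies <- findRepeatCopies(pm$element, pm$genome, minLength = 100)
  expect_equal(length(copies), 6L)
  ov <- GenomicRanges::findOverlaps(copies, pm$truth, ignore.strand = TRUE)
  expect_equal(length(ov), 6L)
  # absent candidate finds nothing
  set.seed(9)
  absent <- DNAString(paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                            collapse = ""))
  expect_length(findRepeatCopies(absent, pm$genome, minLength = 100), 0L)
  # single planted copy is found at its planted coordinates
  one <- plantMite(g0, elementLength = 300, tsdLength = 0, copies = 1, seed = 4)
  hit <- findRepeatCopies(one$element, one$genome, minLength = 100)
  expect_equal(GenomicRanges::start(hit), GenomicRanges::start(one$truth))
})

test_that("element boundaries and TSD are recovered from planted copies", {
  g0 <- simulateAncestralGenome(150000, nGenes = 0, seed = 5)$genome
  pm <- plantMite(g0, elementLength = 350, tsdLength = 3, copies = 12, seed = 7)
  tr <- pm$truth
  cand <- subseq(pm$genome, GenomicRanges::start(tr)[1] - 400,
                 GenomicRanges::end(tr)[1] + 400)
  mod <- modelElement(cand, pm$genome)
  expect_equal(mod@tsdLength, 3L)
  expect_true(as.character(mod@consensus) %in%
              c(as.character(pm$element),
                as.character(reverseComplement(pm$element))))
  ov <- GenomicRanges::findOverlaps(mod@copies, tr, ignore.strand = TRUE)
  expect_equal(length(ov), 12L)
  d <- c(GenomicRanges::start(mod@copies)[S4Vectors::queryHits(ov)] -
           GenomicRanges::start(tr)[S4Vectors::subjectHits(ov)],
         GenomicRanges::end(mod@copies)[S4Vectors::queryHits(ov)] -
           GenomicRanges::end(tr)[S4Vectors::subjectHits(ov)])
  expect_lte(max(abs(d)), 1L)
  # no duplication planted -> TSD 0
  pm0 <- plantMite(g0, elementLength = 350, tsdLength = 0, copies = 8, seed = 8)
  cand0 <- subseq(pm0$genome, GenomicRanges::start(pm0$truth)[1] - 400,
                  GenomicRanges::end(pm0$truth)[1] + 400)
  expect_equal(modelElement(cand0, pm0$genome)@tsdLength, 0L)
  expect_error(defineElementBoundaries(pm0$genome, pm0$truth[1]), "2 copies")
})

test_that("boundary definition is invariant to copy order and strand", {
  g0 <- simulateAncestralGenome(120000, nGenes = 0, seed = 12)$genome
  pm <- plantMite(g0, elementLength = 280, tsdLength = 4, copies = 8, seed = 13)
  cand <- subseq(pm$genome, GenomicRanges::start(pm$truth)[1] - 300,
                 GenomicRanges::end(pm$truth)[1] + 300)
  copies <- findRepeatCopies(cand, pm$genome, minLength = 100)
  m1 <- defineElementBoundaries(pm$genome, copies)
  set.seed(99)
  m2 <- defineElementBoundaries(pm$genome, copies[sample(length(copies))])
  expect_equal(m1@tsdLength, m2@tsdLength)
  expect_equal(as.character(m1@consensus), as.character(m2@consensus))
  expect_equal(sort(GenomicRanges::start(m1@copies)),
               sort(GenomicRanges::start(m2@copies)))
})
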