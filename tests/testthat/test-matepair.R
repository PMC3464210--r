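test_that("reads map uniquely, by strand, and junction reads stay unmapped", {
  set.seed(3)
  ref <- DNAString(paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                         collapse = ""))
  r <- subseq(ref, 101, 136)   # 0-based position 100
  reads <- DNAStringSet(c(fwd = as.character(r),
                          rev = as.character(reverseComplement(r)),
                          novel = paste(rep("ACGT", 9), collapse = "")))
  m <- mapReads(reads, ref)
  expect_equal(m$status[1:2], c("unique", "unique"))
  expect_equal(m$pos[1:2], c(100L, 100L))
  expect_equal(m$strand[1:2], c("+", "-"))
  # a read spanning a junction absent from the reference does not map
  expect_equal(m$status[3], "unmapped")
  # a duplicated sequence multimaps and is excluded from calling
  ref2 <- xscat(ref, subseq(ref, 101, 200))
  m2 <- mapReads(DNAStringSet(c(dup = as.character(r))), ref2)
  expect_equal(m2$status, "multi")
  expect_error(mapReads(reads, DNAString("")), "empty reference")
})

test_that("pair classification follows the FR convention", {
  lib <- librarySpec(2000, insertSd = 100)
  mk <- function(p1, s1, p2, s2) list(
    data.frame(id = "a/1", pos = p1, strand = s1, status = "unique"),
    data.frame(id = "a/2", pos = p2, strand = s2, status = "unique"))
  cls <- function(m) classifyPairs(m[[1]], m[[2]], lib)$class
  expect_equal(cls(mk(1000L, "+", 2964L, "-")), "concordant")      # span = insert
  expect_equal(cls(mk(1000L, "+", 1000L + 20000L, "+")), "inversion_discordant")
  expect_equal(cls(mk(1000L, "-", 20000L, "-")), "inversion_discordant")
  expect_equal(cls(mk(1000L, "+", 1000L + 10 * 2000L, "-")), "distance_discordant")
  expect_equal(cls(mk(2964L, "-", 5000L, "+")), "unresolved")      # RF orientation
  m <- mk(1000L, "+", 2964L, "-"); m[[2]]$status <- "multi"
  expect_equal(cls(m), "unresolved")
})

test_that("a planted inversion yields two reciprocal calls containing the truth", {
  b1 <- 94800L; b2 <- 298400L
  sim <- simulateInversionGenome(400000L, b1, b2, gapLength = 0L, seed = 11)
  libs <- defaultLibraries()
  pairs <- lapply(seq_along(libs), function(k)
    simulateMatePairLibrary(sim$derived, libs[[k]], coverage = 5, seed = 20 + k))
  res <- callBreakpoints(pairs, sim$reference, libs)
  calls <- res$calls
  expect_equal(length(calls), 2L)
  expect_equal(sort(calls$side), c("left", "right"))
  expect_equal(calls$inversion[1], calls$inversion[2])
  maxIns <- max(vapply(libs, function(l) l@insertSize + 3 * l@insertSd, 0))
  for (i in seq_along(calls)) {
    truth <- if (calls$side[i] == "left") b1 else b2
    s0 <- GenomicRanges::start(calls)[i] - 1L
    e0 <- GenomicRanges::end(calls)[i]
    expect_lte(s0, truth)
    expect_gte(e0, truth)
    expect_lte(e0 - s0, maxIns)
  }
  expect_true(all(calls$support >= 2L))
})

test_that("an inversion-free genome produces no calls", {
  sim <- simulateInversionGenome(120000L, 40000L, 80000L, seed = 5)
  lib <- librarySpec(2000, insertSd = 200)
  mp <- simulateMatePairLibrary(sim$reference, lib, coverage = 8, seed = 6)
  m1 <- mapReads(mp$read1, sim$reference)
  m2 <- mapReads(mp$read2, sim$reference)
  cls <- classifyPairs(m1, m2, lib)
  expect_equal(sum(cls$class == "inversion_discordant"), 0L)
  expect_length(clusterAndCall(list(cls)), 0L)
})

test_that("junction gaps beyond the max insert defeat detection", {
  # 6-kb junction gaps with 2/3/5-kb libraries leave no spanning pairs
  res <- detectionLimit(c(0L, 6000L), coverage = 30, seed = 3,
                        flank = 8000L, block = 12000L)
  expect_true(res$detected[res$gap == 0L])
  expect_false(res$detected[res$gap == 6000L])
  # only a 2-kb library: a gap beyond insert - 2*readLength is undetectable
  res2 <- detectionLimit(c(1500L, 2500L),
                         libs = list(librarySpec(2000, insertSd = 0)),
                         coverage = 40, seed = 4,
                         flank = 6000L, block = 8000L)
  expect_true(res2$detected[res2$gap == 1500L])
  expect_false(res2$detected[res2$gap == 2500L])
  expect_error(detectionLimit(1000L, coverage = 0), "positive")
})
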