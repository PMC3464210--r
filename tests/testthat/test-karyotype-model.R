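test_that("segment maps partition arms by distinct breakpoints", {
  cat2 <- catalog2Rop()
  expect_equal(buildSegmentMap(cat2, "2R")@n, 5L)
  full <- gambiaeComplexCatalog()
  expect_equal(buildSegmentMap(full, "2L")@n, 3L)   # one inversion -> 3 segments
  expect_equal(buildSegmentMap(full, "X")@n, 11L)
  one <- subsetCatalog(full, "2La")
  noInv <- inversionCatalog(one@inversions[0, ])
  # arm with no catalogued inversions is a single segment
  expect_equal(buildSegmentMap(noInv, "4")@n, 1L)
  dup <- one@inversions
  dup <- rbind(dup, transform(dup, name = "2La2"))
  expect_error(buildSegmentMap(inversionCatalog(dup), "2L"), "unordered breakpoints")
})

test_that("karyotype encoding composes catalog reversals in a valid order", {
  cat2 <- catalog2Rop()
  expect_equal(permElements(encodeKaryotype(st2R("standard", "standard"), cat2)[["2R"]]),
               1:5)
  expect_equal(permElements(encodeKaryotype(st2R("inverted", "standard"), cat2)[["2R"]]),
               c(1L, -3L, -2L, 4L, 5L))
  expect_equal(permElements(encodeKaryotype(st2R("inverted", "inverted"), cat2)[["2R"]]),
               c(1L, -3L, -4L, 2L, 5L))
  full <- gambiaeComplexCatalog()
  allStd <- setNames(rep("standard", nrow(catalogInversions(full))),
                     catalogInversions(full)$name)
  perms <- encodeKaryotype(allStd, full)
  for (p in perms) expect_equal(permElements(p), seq_along(permElements(p)))
})

test_that("junction adjacencies carry the breakpoint-flanking genes", {
  cat2 <- catalog2Rop()
  map <- buildSegmentMap(cat2, "2R")
  mer <- encodeKaryotype(st2R("inverted", "inverted"), cat2)[["2R"]]
  ja <- junctionAdjacencies(mer, map)
  expect_true(hasAdjacency(ja, "AGAP001760", "AGAP002933"))
  expect_true(hasAdjacency(ja, "AGAP001762", "AGAP002935"))
  jid <- junctionAdjacencies(signedPermutation(1:5, "2R"), map)
  expect_true(hasAdjacency(jid, "AGAP001983", "AGAP001984"))
  expect_true(hasAdjacency(jid, "AGAP003327", "AGAP003328"))
  # breakpoints break reference adjacencies: no junction pair survives a flip
  # at the same junction position
  anc <- encodeKaryotype(st2R("inverted", "standard"), cat2)[["2R"]]
  jaAnc <- junctionAdjacencies(anc, map)
  for (j in c(1L, 3L)) {   # the junctions cut by 2Ro
    pid <- sort(c(jid$anchorLeft[j], jid$anchorRight[j]))
    panc <- sort(c(jaAnc$anchorLeft[j], jaAnc$anchorRight[j]))
    expect_false(identical(pid, panc))
  }
  # single-segment arm has no junctions
  one <- inversionCatalog(catalogInversions(cat2)[0, ])
  m1 <- buildSegmentMap(one, "3R")
  expect_equal(nrow(junctionAdjacencies(signedPermutation(1L, "3R"), m1)), 0L)
})

test_that("overlapping-inversion trajectories obey the contiguity constraint", {
  cat2 <- catalog2Rop()
  # 2Rop -> 2Ro+p -> 2R+o+p is possible
  ok <- validateTrajectory(list(st2R("inverted", "inverted"),
                                st2R("inverted", "standard"),
                                st2R("standard", "standard")), cat2)
  expect_true(ok$valid)
  # 2Rop -> 2R+o p -> 2R+o+p is not possible, in either direction
  seqBad <- list(st2R("inverted", "inverted"),
                 st2R("standard", "inverted"),
                 st2R("standard", "standard"))
  bad <- validateTrajectory(seqBad, cat2)
  expect_false(bad$valid)
  expect_equal(bad$step, 1L)
  expect_equal(bad$inversion, "2Ro")
  badRev <- validateTrajectory(rev(seqBad), cat2)
  expect_false(badRev$valid)
  # direction-independence on the valid sequence too
  okSeq <- list(st2R("inverted", "inverted"), st2R("inverted", "standard"),
                st2R("standard", "standard"))
  expect_equal(validateTrajectory(okSeq, cat2)$valid,
               validateTrajectory(rev(okSeq), cat2)$valid)
  # single state is trivially valid
  expect_true(validateTrajectory(list(st2R("inverted", "inverted")), cat2)$valid)
  # non-elementary step errors
  expect_error(validateTrajectory(list(st2R("standard", "standard"),
                                       st2R("inverted", "inverted")), cat2),
               "non-elementary")
})

test_that("double flip of a non-overlapping inversion is the identity", {
  full <- gambiaeComplexCatalog()
  inv <- catalogInversions(full)$name
  allStd <- setNames(rep("standard", length(inv)), inv)
  for (nm in c("2La", "Xa", "2Rm")) {
    s1 <- allStd; s1[nm] <- "inverted"
    ok <- validateTrajectory(list(allStd, s1, allStd), full)
    expect_true(ok$valid)
  }
})

test_that("valid trajectories replayed as reversals reproduce the encoding", {
  cat2 <- catalog2Rop()
  states <- list(st2R("standard", "standard"), st2R("inverted", "standard"),
                 st2R("inverted", "inverted"))
  expect_true(validateTrajectory(states, cat2)$valid)
  # replay: identity + o-reversal + p-reversal equals the encoded final state
  p <- 1:5
  p <- applyReversal(p, 2, 3)              # 2Ro catalog interval
  p <- applyReversal(p, 3, 4)              # 2Rp junctions in the 2Ro frame
  expect_equal(p, permElements(encodeKaryotype(states[[3]], cat2)[["2R"]]))
})
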