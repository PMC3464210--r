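test_that("topology enumeration yields (2n-5)!! unrooted binary trees", {
  expect_length(enumerateTopologies(letters[1:4]), 3L)
  expect_length(enumerateTopologies(letters[1:5]), 15L)
  expect_length(enumerateTopologies(letters[1:7]), 945L)
  expect_error(enumerateTopologies(letters[1:9]), "3 to 8")
})

test_that("scoreTree matches brute-force parsimony for non-overlapping inversions", {
  for (seed in 1:6) {
    h <- simulateHistory(nIngroup = 4L, nInv = 5L, seed = seed)
    trees <- enumerateTopologies(rownames(h$kmat@states))
    set.seed(seed)
    for (tr in trees[sample(length(trees), 4L)]) {
      sc <- scoreTree(tr, h$kmat)
      expect_equal(sc$totalEvents, bruteForceParsimony(tr, h$kmat))
    }
  }
})

test_that("all-identical leaves score zero events", {
  cat <- toyCatalog(c(A = 2L))
  st <- matrix("standard", 4, 2,
               dimnames = list(paste0("t", 1:4), catalogInversions(cat)$name))
  km <- karyotypeMatrix(st, cat, outgroup = "t1")
  tr <- enumerateTopologies(rownames(st))[[1L]]
  expect_equal(scoreTree(tr, km)$totalEvents, 0L)
})

test_that("the complex's three-scenario analysis singles out Xag", {
  km <- gambiaeKaryotypeMatrix()
  published <- ape::read.tree(text = paste0(
    "(outgroup,(merus,(gambiae,(arabiensis,((quadriannulatusA,",
    "quadriannulatusB),(bwambae,melas))))));"))
  sc <- scoreTree(published, km)
  expect_equal(sc$totalEvents, 10L)
  expect_true(all(sc$origins == 1L))
  # replaying the edge events from the root reproduces every leaf karyotype
  rp <- replayEvents(sc, km)
  expect_identical(unname(rp),
                   unname(km@states[rownames(rp), colnames(rp)] == "inverted"))
})

test_that("event counts respect the origins lower bound", {
  km <- gambiaeKaryotypeMatrix()
  tr <- enumerateTopologies(rownames(km@states))[[1L]]
  sc <- scoreTree(tr, km)
  expect_gte(sc$totalEvents, ncol(km@states))
  expect_equal(sc$totalEvents, sum(sc$origins))
})

test_that("rooting places the root on the outgroup edge", {
  tr <- ape::read.tree(text = "(a,b,(c,d));")
  rt <- rootTree(tr, "c")
  expect_true(ape::is.rooted(rt))
  # the outgroup is a child of the root
  root <- length(rt$tip.label) + 1L
  kids <- rt$edge[rt$edge[, 1L] == root, 2L]
  expect_true(match("c", rt$tip.label) %in% kids)
  expect_error(rootTree(tr, "zz"), "absent")
  # 3-leaf tree has a unique rooting
  tr3 <- ape::read.tree(text = "(a,b,c);")
  expect_true(ape::is.rooted(rootTree(tr3, "a")))
})

test_that("two-taxon scenario reduces to the pairwise distance", {
  cat <- toyCatalog(c(A = 2L))
  st <- matrix(c("standard", "inverted", "standard", "inverted"), 2, 2,
               dimnames = list(c("t1", "out"), catalogInversions(cat)$name))
  km <- karyotypeMatrix(st, cat, outgroup = "out")
  bs <- bestScenario(km, xOptions = "X+")
  expect_equal(bs$scenarios[[1L]]@totalEvents, 2L)
})

test_that("simulated single-origin histories are recovered by the search", {
  for (seed in 1:5) {
    h <- simulateHistory(nIngroup = 6L, nInv = 9L, seed = 100 + seed)
    bs <- bestScenario(h$kmat, xOptions = "X+")
    truth <- canonicalNewick(ape::unroot(h$tree))
    expect_true(truth %in% bs$scenarios[[1L]]@newick)
    # homoplasy-free: the optimum explains every inversion once
    expect_true(any(vapply(bs$scenarios[[1L]]@origins,
                           function(o) all(o[o > 0] == 1L), TRUE)))
  }
})
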