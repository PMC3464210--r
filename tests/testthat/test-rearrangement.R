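test_that("applyReversal flips block order and signs and is an involution", {
  expect_equal(applyReversal(c(1L, 2L, 3L), 2, 3), c(1L, -3L, -2L))
  expect_equal(applyReversal(c(1L, 2L, 3L), 1, 3), c(-3L, -2L, -1L))
  set.seed(1)
  for (k in 1:20) {
    p <- sample(6) * sample(c(-1L, 1L), 6, replace = TRUE)
    a <- sample(6, 1); b <- a + sample.int(7 - a, 1) - 1L
    expect_equal(applyReversal(applyReversal(p, a, b), a, b), p)
  }
  expect_error(applyReversal(1:3, 0, 2), "out of range")
})

test_that("breakpoint-graph distance equals the BFS oracle exhaustively (n <= 4)", {
  for (n in 1:4) {
    for (p in allSignedPerms(n))
      expect_identical(reversalDistance(p), reversalDistanceBFS(p))
  }
})

test_that("distance basics and the gambiae/merus 2R pair", {
  expect_equal(reversalDistance(1:5, 1:5), 0L)
  expect_equal(reversalDistance(c(1L, -2L, 3L), c(1L, 2L, 3L)), 1L)
  # gambiae vs merus 2R differ by the two overlapping inversions
  expect_equal(reversalDistance(c(1L, 2L, 3L, 4L, 5L), c(1L, -3L, -4L, 2L, 5L)), 2L)
  expect_error(reversalDistanceBFS(sample(9) * rep(1L, 9)), "oracle limit")
})

test_that("distance is a metric on random signed permutations", {
  set.seed(42)
  n <- 6
  ps <- replicate(12, sample(n) * sample(c(-1L, 1L), n, replace = TRUE),
                  simplify = FALSE)
  for (i in seq_along(ps)) {
    expect_equal(reversalDistance(ps[[i]], ps[[i]]), 0L)
    for (j in seq_along(ps)) {
      dij <- reversalDistance(ps[[i]], ps[[j]])
      expect_equal(dij, reversalDistance(ps[[j]], ps[[i]]))
      for (k in seq_along(ps))
        expect_lte(dij, reversalDistance(ps[[i]], ps[[k]]) +
                        reversalDistance(ps[[k]], ps[[j]]))
    }
  }
})

test_that("minimal sorting sequences are exhaustive, minimal and constrained", {
  mer <- c(1L, -3L, -4L, 2L, 5L)
  id <- 1:5
  seqs <- minimalSortingSequences(mer, id)
  expect_true(length(seqs) >= 1L)
  for (s in seqs) {
    expect_length(s, 2L)
    cur <- mer
    for (r in s) cur <- applyReversal(cur, r[1] + 1L, r[2] + 1L)
    expect_equal(cur, id)
  }
  # contains undo-p (positions 3..4, 0-based (2,3)) then undo-o ((1,2))
  expect_true(any(vapply(seqs, function(s)
    identical(s[[1]], c(2L, 3L)) && identical(s[[2]], c(1L, 2L)), TRUE)))
  # no optimal sequence starts with the 2Ro catalog interval (segments 2..3,
  # 0-based reversal (1,2)): that order of events is not possible
  expect_false(any(vapply(seqs, function(s) identical(s[[1]], c(1L, 2L)), TRUE)))
  expect_equal(minimalSortingSequences(id, id), list(list()))
})

test_that("pairwise distances add over arms and separate karyotypes correctly", {
  km <- gambiaeKaryotypeMatrix("Xag")
  dm <- pairwiseDistanceMatrix(km)
  expect_equal(unname(diag(dm$total)), rep(0L, nrow(dm$total)))
  expect_equal(dm$total, t(dm$total))
  expect_equal(dm$total["quadriannulatusA", "quadriannulatusB"], 0L)
  expect_equal(dm$total["gambiae", "merus"], 2L)
  expect_equal(dm$byArm[["2R"]]["gambiae", "merus"], 2L)
  # k mutually non-overlapping inversions give distance k
  expect_equal(dm$total["gambiae", "arabiensis"], 5L)   # Xa,Xg vs Xb,Xc,Xd
  expect_equal(dm$total["bwambae", "melas"], 1L)        # 2Rm
})
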