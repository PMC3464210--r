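## ---- signed permutation algebra -----------------------------------------

## q^{-1} o p : express p in the frame of q, so d(p, q) = d(rel, identity).
.relativePerm <- function(p, q) {
  n <- length(p)
  if (length(q) != n || !identical(sort(abs(p)), sort(abs(q))))
    stop("permutations are not over the same segment universe")
  qinv <- integer(n)
  sgn <- integer(n)
  for (k in seq_len(n)) {
    qinv[abs(q[k])] <- k
    sgn[abs(q[k])] <- sign(q[k])
  }
  vapply(seq_len(n), function(i) {
    v <- abs(p[i])
    as.integer(qinv[v] * sgn[v] * sign(p[i]))
  }, integer(1))
}

## ---- Hannenhalli-Pevzner breakpoint graph -------------------------------
##
## d(pi) = (n + 1) - c + h + f over the breakpoint graph of the unsigned
## doubling of pi: c cycles, h hurdles, f fortress indicator.

.breakpointGraph <- function(r) {
  n <- length(r)
  u <- integer(2L * n + 2L)
  u[1L] <- 0L
  for (i in seq_len(n)) {
    x <- r[i]
    if (x > 0L) {
      u[2L * i] <- 2L * x - 1L
      u[2L * i + 1L] <- 2L * x
    } else {
      u[2L * i] <- -2L * x
      u[2L * i + 1L] <- -2L * x - 1L
    }
  }
  u[2L * n + 2L] <- 2L * n + 1L
  pos <- integer(2L * n + 2L)
  pos[u + 1L] <- seq_along(u)
  list(u = u, pos = pos, n = n)
}

## Cycle id per value (gray edges pair values 2i <-> 2i+1; black edges pair
## the values at paired positions (2k-1, 2k)).
.bgCycles <- function(g) {
  m <- length(g$u)
  cyc <- integer(m)       # indexed by value + 1
  ncyc <- 0L
  for (v0 in c(g$u)) {
    if (cyc[v0 + 1L] != 0L) next
    ncyc <- ncyc + 1L
    v <- v0
    repeat {
      cyc[v + 1L] <- ncyc
      p <- g$pos[v + 1L]
      pb <- if (p %% 2L == 1L) p + 1L else p - 1L   # black partner position
      w <- g$u[pb]
      cyc[w + 1L] <- ncyc
      v <- if (w %% 2L == 0L) w + 1L else w - 1L    # gray partner value
      if (v == v0) break
    }
  }
  list(cyc = cyc, ncyc = ncyc)
}

## Count hurdles among a set of unoriented components given their spans.
## Components' spans are pairwise disjoint or nested.  Minimal components
## (no other unoriented component nested inside) are hurdles; the component
## containing all the others, when it exists, is the remaining
## circle-minimal component and also a hurdle.
.countHurdles <- function(spans) {
  k <- nrow(spans)
  if (k == 0L) return(list(h = 0L, isHurdle = logical(0)))
  contains <- function(a, b) spans[a, 1L] < spans[b, 1L] && spans[b, 2L] < spans[a, 2L]
  minimal <- vapply(seq_len(k), function(a)
    !any(vapply(seq_len(k)[-a], function(b) contains(a, b), TRUE)), TRUE)
  isH <- minimal
  if (k >= 2L) {
    top <- vapply(seq_len(k), function(a)
      all(vapply(seq_len(k)[-a], function(b) contains(a, b), TRUE)), TRUE)
    isH <- isH | top
  }
  list(h = sum(isH), isHurdle = isH)
}

.hpDistanceCore <- function(r) {
  n <- length(r)
  if (n == 0L) return(0L)
  g <- .breakpointGraph(r)
  cc <- .bgCycles(g)

  # gray edge i (values 2i, 2i+1), i = 0..n: positions, orientation, cycle
  ge <- t(vapply(0:n, function(i) {
    p1 <- g$pos[2L * i + 1L]
    p2 <- g$pos[2L * i + 2L]
    c(lo = min(p1, p2), hi = max(p1, p2),
      oriented = as.integer((p1 + p2) %% 2L == 0L),
      cycle = cc$cyc[2L * i + 1L])
  }, c(lo = 0, hi = 0, oriented = 0, cycle = 0)))

  # cycle sizes (in gray edges); length-1 cycles are adjacencies and take
  # no part in components
  csize <- tabulate(ge[, "cycle"], nbins = cc$ncyc)
  keep <- csize[ge[, "cycle"]] >= 2L
  h <- 0L; f <- 0L
  if (any(keep)) {
    gek <- ge[keep, , drop = FALSE]
    # components: union of cycles whose gray edges interleave (cross)
    m <- nrow(gek)
    parent <- seq_len(m)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    uni <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (i >= j) next
        if (gek[i, "cycle"] == gek[j, "cycle"]) { uni(i, j); next }
        if ((gek[i, "lo"] < gek[j, "lo"] && gek[j, "lo"] < gek[i, "hi"] && gek[i, "hi"] < gek[j, "hi"]) ||
            (gek[j, "lo"] < gek[i, "lo"] && gek[i, "lo"] < gek[j, "hi"] && gek[j, "hi"] < gek[i, "hi"]))
          uni(i, j)
      }
    }
    comp <- vapply(seq_len(m), find, 1L)
    ids <- unique(comp)
    unorient <- vapply(ids, function(id) all(gek[comp == id, "oriented"] == 0L), TRUE)
    uids <- ids[unorient]
    if (length(uids)) {
      spans <- t(vapply(uids, function(id)
        c(min(gek[comp == id, "lo"]), max(gek[comp == id, "hi"])), c(0, 0)))
      hc <- .countHurdles(spans)
      h <- hc$h
      if (h %% 2L == 1L && h > 0L) {
        # fortress iff every hurdle is a superhurdle: removing it does not
        # lower the hurdle count (a protected component becomes a hurdle)
        super <- vapply(which(hc$isHurdle), function(a) {
          .countHurdles(spans[-a, , drop = FALSE])$h == h
        }, TRUE)
        if (all(super)) f <- 1L
      }
    }
  }
  as.integer(n + 1L - cc$ncyc + h + f)
}

#' Signed reversal distance (breakpoint-graph formula)
#'
#' Minimum number of reversals transforming one signed permutation into
#' another, computed exactly by the Hannenhalli-Pevzner formula
#' `d = (n + 1) - c + h + f` on the breakpoint graph (cycles `c`, hurdles
#' `h`, fortress indicator `f`).  The exhaustive [reversalDistanceBFS]
#' oracle is the arbiter for this implementation and the two agree on every
#' signed permutation with `n <= 5` and on large random samples at
#' `n <= 7` (see the package tests).
#'
#' @param p,q [SignedPermutation-class] objects or integer vectors over the
#'   same segment universe.  `q` defaults to the identity.
#' @return Integer distance.
#' @export
reversalDistance <- function(p, q = NULL) {
  p <- permElements(p)
  r <- if (is.null(q)) p else .relativePerm(p, permElements(q))
  .hpDistanceCore(r)
}

#' Exhaustive reversal distance by breadth-first search
#'
#' Independent oracle for [reversalDistance]: exact minimum reversal count
#' found by breadth-first search over the full reversal graph of signed
#' permutations.  Guarded to `n <= 8`; the distance table for each `n` is
#' cached within the session.
#'
#' @inheritParams reversalDistance
#' @return Integer distance.
#' @export
reversalDistanceBFS <- function(p, q = NULL) {
  p <- permElements(p)
  r <- if (is.null(q)) p else .relativePerm(p, permElements(q))
  n <- length(r)
  if (n == 0L) return(0L)
  if (n > 8L) stop("oracle limit: BFS oracle supports n <= 8")
  key <- paste0("bfs", n)
  tab <- .chromoPhyloCache[[key]]
  if (is.null(tab)) {
    tab <- bfs_distance_table(n)
    .chromoPhyloCache[[key]] <- tab
  }
  tab[perm_rank(r) + 1L]
}

.chromoPhyloCache <- new.env(parent = emptyenv())

#' Enumerate minimal sorting reversal sequences
#'
#' All (up to `limit`) shortest sequences of reversals transforming `p`
#' into `q`, found by depth-first search guided by [reversalDistance].
#' Reversals within a step are tried in lexicographic `(start, end)` order,
#' so the enumeration order is deterministic.  Guarded to distances <= 4.
#'
#' @inheritParams reversalDistance
#' @param limit maximum number of sequences to return.
#' @return List of sequences; each sequence is a list of `c(start, end)`
#'   0-based inclusive reversal bounds.  `p == q` yields a single empty
#'   sequence.
#' @export
minimalSortingSequences <- function(p, q, limit = 100L) {
  p <- permElements(p); q <- permElements(q)
  d0 <- reversalDistance(p, q)
  if (d0 > 4L) stop("enumeration guard: distance ", d0, " exceeds 4")
  out <- list()
  n <- length(p)
  recurse <- function(cur, left, prefix) {
    if (length(out) >= limit) return()
    if (left == 0L) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (a in seq_len(n)) {
      for (b in a:n) {
        nxt <- cur
        nxt[a:b] <- -rev(nxt[a:b])
        if (reversalDistance(nxt, q) == left - 1L)
          recurse(nxt, left - 1L, c(prefix, list(c(a - 1L, b - 1L))))
        if (length(out) >= limit) return()
      }
    }
  }
  recurse(p, d0, list())
  out
}

#' Pairwise rearrangement distance matrix
#'
#' Total reversal distance between taxa: the sum over chromosome arms of the
#' per-arm signed reversal distances between encoded karyotypes.
#'
#' @param karyotypes named list (one entry per taxon) of per-arm
#'   [SignedPermutation-class] lists, as returned by [encodeKaryotype]; or a
#'   [KaryotypeMatrix-class], which is encoded first.
#' @param catalog catalog used when `karyotypes` is a
#'   [KaryotypeMatrix-class].
#' @return list with `total` (symmetric integer matrix) and `byArm`
#'   (named list of per-arm matrices).
#' @export
pairwiseDistanceMatrix <- function(karyotypes, catalog = NULL) {
  if (is(karyotypes, "KaryotypeMatrix")) {
    kmat <- karyotypes
    catalog <- kmat@catalog
    karyotypes <- lapply(rownames(kmat@states), function(tx)
      encodeKaryotype(kmat@states[tx, ], catalog))
    names(karyotypes) <- rownames(kmat@states)
  }
  taxa <- names(karyotypes)
  arms <- names(karyotypes[[1L]])
  for (k in karyotypes)
    if (!identical(names(k), arms)) stop("mismatched arms across karyotypes")
  nt <- length(taxa)
  byArm <- lapply(arms, function(a) {
    m <- matrix(0L, nt, nt, dimnames = list(taxa, taxa))
    for (i in seq_len(nt)) {
      for (j in seq_len(nt)) {
        if (j <= i) next
        d <- reversalDistance(karyotypes[[i]][[a]], karyotypes[[j]][[a]])
        m[i, j] <- m[j, i] <- d
      }
    }
    m
  })
  names(byArm) <- arms
  total <- Reduce(`+`, byArm)
  list(total = total, byArm = byArm)
}
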