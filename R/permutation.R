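#' Construct a signed permutation
#'
#' @param elements integer vector of signed segment ids.
#' @param arm arm identifier.
#' @return A [SignedPermutation-class].
#' @export
signedPermutation <- function(elements, arm = "arm") {
  new("SignedPermutation", arm = arm, elements = as.integer(elements))
}

#' Elements of a signed permutation
#' @param perm a [SignedPermutation-class] or integer vector.
#' @return Integer vector of signed elements.
#' @export
permElements <- function(perm) {
  if (is(perm, "SignedPermutation")) perm@elements else as.integer(perm)
}

#' Apply a reversal to a signed permutation
#'
#' Reverses the order of the block `start..end` (1-based, inclusive) and
#' flips every sign within it.  Applying the same reversal twice restores
#' the original permutation.
#'
#' @param perm a [SignedPermutation-class] or integer vector.
#' @param start,end 1-based inclusive block bounds.
#' @return Object of the same kind as `perm`.
#' @export
applyReversal <- function(perm, start, end) {
  p <- permElements(perm)
  n <- length(p)
  if (start < 1L || end > n || start > end) stop("reversal out of range")
  p[start:end] <- -rev(p[start:end])
  if (is(perm, "SignedPermutation")) initialize(perm, elements = p) else p
}

## ---- breakpoint-junction machinery --------------------------------------
##
## Junction j of the reference frame is the point between reference segments
## j and j+1.  In a rearranged permutation that junction is intact iff the
## two segment ends flanking it are adjacent with the reference-local
## orientation, i.e. the permutation contains the consecutive pair
## (j, j+1) or (-(j+1), -j).

## Junction index restored by the consecutive pair (x, y), or NA.
.pairJunction <- function(x, y) {
  if (y == x + 1L) {
    if (x > 0L) return(x)          # (j, j+1)
    if (y < 0L) return(-x - 1L)    # (-(j+1), -j)
  }
  NA_integer_
}

## Cut position (between positions k and k+1) at which junction j is intact
## in p, or NA if the junction is broken.
.junctionCut <- function(p, j) {
  n <- length(p)
  if (n < 2L) return(NA_integer_)
  for (k in seq_len(n - 1L)) {
    jj <- .pairJunction(p[k], p[k + 1L])
    if (!is.na(jj) && jj == j) return(k)
  }
  NA_integer_
}

## Flip one inversion (junctions j1, j2) on permutation p.
##
## standard -> inverted: both junctions must be intact; the flip is the
## reversal cutting exactly at them.
## inverted -> standard: the flip is the (first, lexicographic) reversal
## whose two newly created adjacencies are exactly the two junctions.
## Returns the flipped permutation, or NULL if no valid flip exists.
.flipPerm <- function(p, j1, j2, toInverted) {
  n <- length(p)
  if (toInverted) {
    k1 <- .junctionCut(p, j1)
    k2 <- .junctionCut(p, j2)
    if (is.na(k1) || is.na(k2) || k1 == k2) return(NULL)
    a <- min(k1, k2) + 1L
    b <- max(k1, k2)
    p[a:b] <- -rev(p[a:b])
    return(p)
  }
  for (a in seq_len(n)) {
    for (b in a:n) {
      left <- if (a > 1L) .pairJunction(p[a - 1L], -p[b]) else NA_integer_
      right <- if (b < n) .pairJunction(-p[a], p[b + 1L]) else NA_integer_
      if (!is.na(left) && !is.na(right) &&
          ((left == j1 && right == j2) || (left == j2 && right == j1))) {
        p[a:b] <- -rev(p[a:b])
        return(p)
      }
    }
  }
  NULL
}

## Flip inversion `name` given its current state; NULL when invalid.
.flipInversion <- function(p, catalog, map, name, currentState) {
  j <- .inversionJunctions(catalog, map, name)
  .flipPerm(p, j[[1L]], j[[2L]], toInverted = identical(currentState, "standard"))
}

## All permutations of seq_len(k), rows in lexicographic order.
.permutationsOf <- function(k) {
  if (k == 0L) return(matrix(integer(), nrow = 1L, ncol = 0L))
  if (k == 1L) return(matrix(1L))
  sub <- .permutationsOf(k - 1L)
  out <- NULL
  for (first in seq_len(k)) {
    rest <- setdiff(seq_len(k), first)
    out <- rbind(out, cbind(first, matrix(rest[sub], nrow = nrow(sub))))
  }
  unname(out)
}

#' Encode arrangement states as signed permutations
#'
#' Starting from the identity (all-standard reference frame), the catalogued
#' reversal of every inversion in the `"inverted"` state is composed, in
#' catalog order when that order is valid and otherwise in the first valid
#' order.  A flip is valid only when the inversion's two breakpoint junctions
#' can be cut in the current permutation (see [validateTrajectory]); for
#' overlapping inversions this constrains, and can forbid, composition
#' orders.
#'
#' @param states named character vector (or single-row portion of a
#'   [KaryotypeMatrix-class]) of `"standard"`/`"inverted"` states covering
#'   every catalog inversion.
#' @param catalog an [InversionCatalog-class].
#' @param arms arms to encode (default: all catalog arms).
#' @return Named list of [SignedPermutation-class], one per arm.
#' @export
encodeKaryotype <- function(states, catalog, arms = catalogArms(catalog)) {
  inv <- catalog@inversions
  missing <- setdiff(inv$name[inv$arm %in% arms], names(states))
  if (length(missing))
    stop("states missing for inversion(s): ", paste(missing, collapse = ", "))
  out <- lapply(arms, function(arm) {
    map <- buildSegmentMap(catalog, arm)
    armInv <- inv$name[inv$arm == arm]
    flips <- armInv[!is.na(states[armInv]) & states[armInv] == "inverted"]
    p <- seq_len(map@n)
    if (length(flips)) {
      ords <- .permutationsOf(length(flips))
      done <- FALSE
      for (r in seq_len(nrow(ords))) {
        q <- p
        ok <- TRUE
        for (nm in flips[ords[r, ]]) {
          q <- .flipInversion(q, catalog, map, nm, "standard")
          if (is.null(q)) { ok <- FALSE; break }
        }
        if (ok) { p <- q; done <- TRUE; break }
      }
      if (!done)
        stop("inconsistent overlapping states on arm ", arm, ": no valid composition order for ",
             paste(flips, collapse = "+"))
    }
    signedPermutation(p, arm)
  })
  names(out) <- arms
  out
}

#' Gene-anchor adjacencies at segment junctions
#'
#' Reads a signed permutation left to right (telomere to centromere) and
#' reports, for each internal junction between consecutive segments, the
#' ordered pair of gene anchors meeting there: the anchor at the trailing
#' end of the left segment and the anchor at the leading end of the right
#' segment, respecting segment orientation.
#'
#' @param perm a [SignedPermutation-class] or integer vector.
#' @param map the arm's [SegmentMap-class].
#' @return data.frame with columns `junction` (position index), `anchorLeft`,
#'   `anchorRight`, `segLeft`, `segRight`.  Zero rows for a single-segment
#'   arm.
#' @export
junctionAdjacencies <- function(perm, map) {
  p <- permElements(perm)
  if (length(p) != map@n) stop("permutation does not match map")
  anch <- .segmentAnchors(map)
  endAnchor <- function(x, side) {
    s <- abs(x)
    # trailing ("right") end of an element, or leading ("left") end
    if (side == "right") {
      if (x > 0L) anch$right[s] else anch$left[s]
    } else {
      if (x > 0L) anch$left[s] else anch$right[s]
    }
  }
  k <- length(p) - 1L
  if (k < 1L)
    return(data.frame(junction = integer(), anchorLeft = character(),
                      anchorRight = character(), segLeft = integer(),
                      segRight = integer(), stringsAsFactors = FALSE))
  data.frame(
    junction = seq_len(k),
    anchorLeft = vapply(seq_len(k), function(i) endAnchor(p[i], "right"), ""),
    anchorRight = vapply(seq_len(k), function(i) endAnchor(p[i + 1L], "left"), ""),
    segLeft = p[seq_len(k)],
    segRight = p[seq_len(k) + 1L],
    stringsAsFactors = FALSE
  )
}

#' Test whether a junction table contains an anchor adjacency
#'
#' Adjacencies are compared without orientation: the pair is present whether
#' read telomere-to-centromere or the reverse.
#'
#' @param adjacencies output of [junctionAdjacencies].
#' @param a,b anchor identifiers.
#' @return Logical.
#' @export
hasAdjacency <- function(adjacencies, a, b) {
  any((adjacencies$anchorLeft == a & adjacencies$anchorRight == b) |
      (adjacencies$anchorLeft == b & adjacencies$anchorRight == a))
}

#' Validate a trajectory of arrangement states
#'
#' Checks that a sequence of karyotype states is realisable by successive
#' single paracentric inversions.  Consecutive states must differ by exactly
#' one inversion's state flip; each flip must cut the flipped inversion's
#' breakpoint junctions in the current permutation (so, for overlapping
#' inversions, only certain orders of events are possible); and the replayed
#' permutation must arrive at the canonical encoding of the final state.
#' The check is direction-independent: a trajectory is valid iff its
#' reversal is valid.
#'
#' @param stateSequence list of named state vectors (each as in
#'   [encodeKaryotype]).
#' @param catalog an [InversionCatalog-class].
#' @param arms arms to check (default: all).
#' @return list with elements `valid` (logical), and on failure `step`
#'   (index of the first violating transition), `inversion` and `reason`.
#' @export
validateTrajectory <- function(stateSequence, catalog,
                               arms = catalogArms(catalog)) {
  if (length(stateSequence) < 1L) stop("empty state sequence")
  if (length(stateSequence) == 1L) return(list(valid = TRUE))
  inv <- catalog@inversions
  armNames <- lapply(arms, function(a) inv$name[inv$arm == a])
  names(armNames) <- arms
  maps <- lapply(arms, function(a) buildSegmentMap(catalog, a))
  names(maps) <- arms

  perms <- lapply(encodeKaryotype(stateSequence[[1L]], catalog, arms), permElements)
  for (i in seq_len(length(stateSequence) - 1L)) {
    s0 <- stateSequence[[i]]
    s1 <- stateSequence[[i + 1L]]
    all_names <- unlist(armNames, use.names = FALSE)
    changed <- all_names[s0[all_names] != s1[all_names]]
    if (length(changed) != 1L)
      stop("non-elementary step at transition ", i, ": ",
           length(changed), " states differ")
    arm <- inv$arm[inv$name == changed]
    q <- .flipInversion(perms[[arm]], catalog, maps[[arm]], changed,
                        unname(s0[changed]))
    if (is.null(q))
      return(list(valid = FALSE, step = i, inversion = changed,
                  reason = sprintf(
                    "flip of %s is not permutation-contiguous at step %d", changed, i)))
    perms[[arm]] <- q
  }
  final <- lapply(encodeKaryotype(stateSequence[[length(stateSequence)]],
                                  catalog, arms), permElements)
  for (arm in arms) {
    if (!identical(perms[[arm]], final[[arm]]))
      return(list(valid = FALSE, step = length(stateSequence) - 1L,
                  inversion = NA_character_,
                  reason = sprintf(
                    "replayed arrangement on arm %s does not reach the attested junctions of the final state", arm)))
  }
  list(valid = TRUE)
}
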