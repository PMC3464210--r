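#' Construct a mate-pair library specification
#'
#' @param insertSize nominal insert size in bp.
#' @param insertSd insert-size standard deviation (default 10% of the
#'   insert).
#' @param readLength read length in bp.
#' @param orientation pair-orientation convention (`"FR"`).
#' @return A [LibrarySpec-class].
#' @export
librarySpec <- function(insertSize, insertSd = 0.1 * insertSize,
                        readLength = 36L, orientation = "FR") {
  new("LibrarySpec", insertSize = insertSize, insertSd = insertSd,
      readLength = as.integer(readLength), orientation = orientation)
}

#' Default 2/3/5-kb mate-pair libraries
#'
#' @param insertSd standard deviations (recycled); default 10% of each
#'   insert.
#' @return Named list of [LibrarySpec-class].
#' @export
defaultLibraries <- function(insertSd = NULL) {
  sizes <- c(2000, 3000, 5000)
  if (is.null(insertSd)) insertSd <- 0.1 * sizes
  insertSd <- rep_len(insertSd, length(sizes))
  out <- mapply(function(s, sd) librarySpec(s, sd), sizes, insertSd)
  names(out) <- paste0("lib", sizes %/% 1000, "kb")
  out
}

#' Map reads to a reference by unique exact matching
#'
#' A read maps if and only if it has exactly one exact full-length
#' occurrence in the reference, forward or reverse complement.  Matching is
#' seeded on the first `seedLength` bases (Aho-Corasick via
#' [Biostrings::matchPDict]) and verified over the full read; reads with no
#' occurrence are `unmapped`, reads with several are `multi` and excluded
#' from calling.
#'
#' @param reads [Biostrings::DNAStringSet] of equal-width reads.
#' @param reference [Biostrings::DNAString].
#' @param seedLength seed width in bp (<= read length).
#' @param chunkSize reads per matching chunk (memory control).
#' @return data.frame with `id`, `pos` (0-based start on the reference, NA
#'   unless unique), `strand`, `status` (`unique`/`multi`/`unmapped`).
#' @export
mapReads <- function(reads, reference, seedLength = 20L, chunkSize = 250000L) {
  if (length(reference) == 0L) stop("empty reference")
  w <- unique(Biostrings::width(reads))
  if (length(w) != 1L) stop("reads must have equal width")
  if (w < seedLength) stop("read length must be >= seed length")
  L <- length(reference)
  refRC <- Biostrings::reverseComplement(reference)
  n <- length(reads)
  nhits <- integer(n)
  pos <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  idx0 <- 0L
  while (idx0 < n) {
    take <- seq.int(idx0 + 1L, min(idx0 + chunkSize, n))
    sub <- reads[take]
    subChar <- as.character(sub)
    pd <- Biostrings::PDict(Biostrings::subseq(sub, 1L, seedLength))
    for (str in c("+", "-")) {
      subject <- if (str == "+") reference else refRC
      m <- Biostrings::matchPDict(pd, subject)
      si <- Biostrings::startIndex(m)
      hitRead <- rep.int(seq_along(sub), lengths(si))
      hitPos <- unlist(si, use.names = FALSE)
      if (!length(hitPos)) next
      keep <- hitPos + w - 1L <= L
      hitRead <- hitRead[keep]; hitPos <- hitPos[keep]
      if (!length(hitPos)) next
      refStr <- as.character(Biostrings::DNAStringSet(
        Biostrings::Views(subject, start = hitPos, width = w)))
      ok <- refStr == subChar[hitRead]
      hitRead <- hitRead[ok]; hitPos <- hitPos[ok]
      if (!length(hitPos)) next
      g <- take[hitRead]
      cnt <- tabulate(hitRead, nbins = length(sub))
      nhits[take] <- nhits[take] + cnt
      first <- !duplicated(hitRead)
      gi <- g[first]
      p1 <- hitPos[first]
      if (str == "+") {
        newpos <- p1 - 1L
      } else {
        newpos <- L - (p1 - 1L) - w   # 0-based start on the forward strand
      }
      assign_ok <- is.na(pos[gi])
      pos[gi[assign_ok]] <- newpos[assign_ok]
      strand[gi[assign_ok]] <- str
    }
    idx0 <- idx0 + chunkSize
  }
  status <- ifelse(nhits == 0L, "unmapped", ifelse(nhits == 1L, "unique", "multi"))
  pos[status != "unique"] <- NA_integer_
  strand[status != "unique"] <- NA_character_
  data.frame(id = if (!is.null(names(reads))) names(reads) else as.character(seq_len(n)),
             pos = pos, strand = strand, status = status,
             stringsAsFactors = FALSE)
}

#' Classify mapped read pairs
#'
#' Under the FR convention a pair is `concordant` when the forward-strand
#' read lies upstream of the reverse-strand read and the outer span is
#' within `insertSize +/- maxInsertFactor * insertSd`; pairs mapping on the
#' same strand are `inversion_discordant`; correctly oriented pairs whose
#' span exceeds the window are `distance_discordant`; anything else
#' (non-unique mapping, reversed orientation, too-short span) is
#' `unresolved`.
#'
#' @param map1,map2 mapped read tables from [mapReads] (parallel rows =
#'   pairs).
#' @param lib the pairs' [LibrarySpec-class].
#' @param maxInsertFactor half-width of the concordance window in units of
#'   `insertSd`.
#' @return data.frame per pair: `class`, `left`, `right` (0-based outer
#'   positions), `span`, `strandClass` (`++`/`--` for same-strand pairs),
#'   `maxInsert`.
#' @export
classifyPairs <- function(map1, map2, lib, maxInsertFactor = 3) {
  stopifnot(nrow(map1) == nrow(map2))
  rl <- lib@readLength
  maxIns <- lib@insertSize + maxInsertFactor * lib@insertSd
  minIns <- lib@insertSize - maxInsertFactor * lib@insertSd
  n <- nrow(map1)
  left <- pmin(map1$pos, map2$pos)
  right <- pmax(map1$pos, map2$pos)
  span <- right + rl - left
  cls <- rep("unresolved", n)
  both <- map1$status == "unique" & map2$status == "unique"
  same <- both & map1$strand == map2$strand
  cls[same] <- "inversion_discordant"
  opp <- both & !same
  # FR: the + read must start at or before the - read
  plusPos <- ifelse(map1$strand == "+", map1$pos, map2$pos)
  minusPos <- ifelse(map1$strand == "-", map1$pos, map2$pos)
  fr <- opp & plusPos <= minusPos
  inWin <- fr & span >= minIns & span <= maxIns
  cls[inWin] <- "concordant"
  cls[fr & span > maxIns] <- "distance_discordant"
  strandClass <- rep(NA_character_, n)
  strandClass[same] <- paste0(map1$strand[same], map2$strand[same])
  data.frame(class = cls, left = left, right = right, span = span,
             strandClass = strandClass, maxInsert = maxIns,
             stringsAsFactors = FALSE)
}

## Single-linkage clustering of (left, right) pairs within `linkDist` on
## both coordinates.  Returns a cluster index per row.
.clusterPairs <- function(left, right, linkDist) {
  n <- length(left)
  cl <- integer(n)
  o <- order(left, right)
  nclust <- 0L
  bounds <- list()   # per cluster: c(minL, maxL, minR, maxR)
  for (i in o) {
    hit <- 0L
    for (k in seq_len(nclust)) {
      b <- bounds[[k]]
      if (left[i] >= b[1L] - linkDist && left[i] <= b[2L] + linkDist &&
          right[i] >= b[3L] - linkDist && right[i] <= b[4L] + linkDist) {
        hit <- k; break
      }
    }
    if (hit == 0L) {
      nclust <- nclust + 1L
      hit <- nclust
      bounds[[hit]] <- c(left[i], left[i], right[i], right[i])
    } else {
      b <- bounds[[hit]]
      bounds[[hit]] <- c(min(b[1L], left[i]), max(b[2L], left[i]),
                         min(b[3L], right[i]), max(b[4L], right[i]))
    }
    cl[i] <- hit
  }
  cl
}

#' Cluster same-orientation discordant pairs and call inversion breakpoints
#'
#' Same-strand pairs delineate an inversion: `++` pairs span the left
#' derived junction (read 1 before the left breakpoint `b1`, read 2 inside
#' the inverted block near the right breakpoint `b2`) and `--` pairs span
#' the right junction (read 1 inside the block near `b1`, read 2 beyond
#' `b2`).  All same-strand pairs of one inversion share footprints within
#' one maximal insert and are clustered together; each supported cluster
#' yields two reciprocal breakpoint calls by intersecting the pairs' hard
#' geometric constraints — for a read length `rl`,
#' `b1 >= max(p) + rl` and `b2 >= max(r) + rl` from the `++` pairs
#' (positions `p`, `r`) and `b1 <= min(u)`, `b2 <= min(v)` from the `--`
#' pairs (positions `u`, `v`) — none of which depend on the insert-size
#' distribution.  When only one strand class supports a cluster the missing
#' bound falls back to the insert-based footprint, and intervals are capped
#' at one maximal insert.
#'
#' Reads overhanging a novel junction by `k` bases still map, shifted, when
#' the flanking bases coincide by chance (probability `4^-k`), so the
#' extreme-value bounds carry a small guard band (`junctionSlack`, default
#' 12 bp, violation probability about `4e-8` per read).
#'
#' @param classified classified pair table(s) from [classifyPairs]; a list
#'   is concatenated (e.g. one element per library).
#' @param readLength read length in bp.
#' @param minSupport minimum supporting pairs per cluster.
#' @param refName reference sequence name for the output ranges.
#' @param junctionSlack guard band around footprint bounds, in bp.
#' @return [GenomicRanges::GRanges] of breakpoint intervals (0-based,
#'   half-open internally, reported via the 1-based GRanges convention) with
#'   metadata `inversion` (id pairing the two reciprocal calls), `side`,
#'   `support`.
#' @export
clusterAndCall <- function(classified, readLength = 36L, minSupport = 2L,
                           refName = "ref", junctionSlack = 12L) {
  if (is.data.frame(classified)) classified <- list(classified)
  cc <- do.call(rbind, classified)
  cc <- cc[cc$class == "inversion_discordant", , drop = FALSE]
  empty <- GenomicRanges::GRanges(seqnames = character(), ranges = IRanges::IRanges(),
                                  inversion = integer(), side = character(),
                                  support = integer())
  if (!nrow(cc)) return(empty)
  rl <- readLength
  cl <- .clusterPairs(cc$left, cc$right, linkDist = max(cc$maxInsert))
  gr <- NULL
  inv <- 0L
  for (k in unique(cl)) {
    s <- cc[cl == k, , drop = FALSE]
    if (nrow(s) < minSupport) next
    Imax <- max(s$maxInsert)
    pp <- s[s$strandClass == "++", , drop = FALSE]
    mm <- s[s$strandClass == "--", , drop = FALSE]
    # left breakpoint b1
    b1lo <- if (nrow(pp)) max(pp$left) + rl else max(max(mm$left) - Imax + rl, 0)
    b1hi <- if (nrow(mm)) min(mm$left) + 1 else min(pp$left) + Imax
    # right breakpoint b2
    b2lo <- max(if (nrow(pp)) max(pp$right) + rl else 0,
                if (nrow(mm)) max(mm$left) + rl else 0)
    b2hi <- if (nrow(mm)) min(mm$right) + 1 else min(pp$right) + Imax
    b1lo <- max(b1lo - junctionSlack, 0)
    b2lo <- max(b2lo - junctionSlack, 0)
    b1hi <- b1hi + junctionSlack
    b2hi <- b2hi + junctionSlack
    # cap at one maximal insert (soft-bound clusters can be wide)
    b1hi <- min(b1hi, b1lo + Imax)
    b2hi <- min(b2hi, b2lo + Imax)
    if (b1hi <= b1lo || b2hi <= b2lo) next
    inv <- inv + 1L
    gr <- rbind(gr, data.frame(
      inversion = inv, side = c("left", "right"),
      start0 = c(b1lo, b2lo), end0 = c(b1hi, b2hi), support = nrow(s)))
  }
  if (is.null(gr)) return(empty)
  out <- GenomicRanges::GRanges(refName,
    IRanges::IRanges(start = gr$start0 + 1L, end = gr$end0))
  out$inversion <- gr$inversion
  out$side <- gr$side
  out$support <- gr$support
  out
}

#' Detect inversion breakpoints from mate-pair libraries
#'
#' End-to-end wrapper: simulates nothing, takes read pairs per library, maps
#' both mates, classifies pairs and calls breakpoints.
#'
#' @param pairs named list, one element per library, each a list with
#'   `read1`, `read2` ([Biostrings::DNAStringSet]).
#' @param reference [Biostrings::DNAString].
#' @param libs parallel list of [LibrarySpec-class].
#' @param minSupport minimum supporting pairs per cluster.
#' @param maxInsertFactor concordance window half-width in sd units.
#' @param refName reference name in the output.
#' @return list with `calls` ([GenomicRanges::GRanges]), `classified`
#'   (per-library pair tables) and `maps` (per-library mate mapping tables).
#' @export
callBreakpoints <- function(pairs, reference, libs, minSupport = 2L,
                            maxInsertFactor = 3, refName = "ref") {
  stopifnot(length(pairs) == length(libs))
  classified <- vector("list", length(libs))
  maps <- vector("list", length(libs))
  for (k in seq_along(libs)) {
    m1 <- mapReads(pairs[[k]]$read1, reference)
    m2 <- mapReads(pairs[[k]]$read2, reference)
    classified[[k]] <- classifyPairs(m1, m2, libs[[k]], maxInsertFactor)
    maps[[k]] <- list(read1 = m1, read2 = m2)
  }
  rl <- libs[[1L]]@readLength
  calls <- clusterAndCall(classified, readLength = rl, minSupport = minSupport,
                          refName = refName)
  list(calls = calls, classified = classified, maps = maps)
}

#' Junction-gap detection limit of mate-pair libraries
#'
#' For each junction-gap length, simulates a reference and a derived genome
#' whose inversion junctions carry novel "breakpoint region" sequence of
#' that length, generates mate pairs from every library, and reports whether
#' at least one same-orientation pair spans a junction.  A junction with gap
#' `g` is geometrically detectable iff some library satisfies
#' `insertSize >= g + 2 * readLength`; the default libraries use fixed-size
#' inserts (sd 0) so the simulation isolates exactly this limit.
#'
#' @param gapLengths junction gap lengths in bp.
#' @param libs list of [LibrarySpec-class] (default: fixed-insert 2/3/5-kb
#'   libraries).
#' @param coverage per-library read coverage.
#' @param seed RNG seed.
#' @param flank,block lengths of the flanking and inverted blocks of the toy
#'   genome.
#' @return data.frame with `gap`, `detected`, `nSpanningPairs`.
#' @export
detectionLimit <- function(gapLengths, libs = defaultLibraries(insertSd = 0),
                           coverage = 50, seed = 1L,
                           flank = 15000L, block = 20000L) {
  if (coverage <= 0) stop("coverage must be positive")
  res <- NULL
  for (gi in seq_along(gapLengths)) {
    g <- as.integer(gapLengths[gi])
    sim <- simulateInversionGenome(2L * flank + block, flank, flank + block,
                                   gapLength = g, seed = seed + gi)
    ndisc <- 0L
    for (k in seq_along(libs)) {
      mp <- simulateMatePairLibrary(sim$derived, libs[[k]], coverage,
                                    seed = seed + 1000L * k + gi)
      m1 <- mapReads(mp$read1, sim$reference)
      m2 <- mapReads(mp$read2, sim$reference)
      cls <- classifyPairs(m1, m2, libs[[k]])
      ndisc <- ndisc + sum(cls$class == "inversion_discordant")
    }
    res <- rbind(res, data.frame(gap = g, detected = ndisc > 0L,
                                 nSpanningPairs = ndisc))
  }
  res
}
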