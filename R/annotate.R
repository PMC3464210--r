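#' Diagnostic junction models for an inversion's two arrangement states
#'
#' The gene-anchor adjacencies that distinguish an inversion's states: pairs
#' occurring at some junction of an arrangement carrying the inversion but
#' of no arrangement without it (`inverted`), and vice versa (`standard`).
#' For an isolated inversion these are simply the standard breakpoint pairs
#' (distal-telomeric with distal-centromeric, proximal likewise) versus the
#' inverted pairs joining the two breakpoints; for overlapping inversions
#' the attested junctions depend on the arrangement background (e.g. the
#' 2Rp junctions realised on the 2Ro background differ from those on the
#' standard background), so the models are derived from every arrangement
#' reachable by valid flips.
#'
#' @param catalog an [InversionCatalog-class].
#' @param name inversion name.
#' @return list with `standard` and `inverted`, each a 2-column matrix of
#'   anchor pairs (orientation-free).
#' @export
junctionModels <- function(catalog, name) {
  inv <- catalog@inversions[catalog@inversions$name == name, , drop = FALSE]
  if (nrow(inv) != 1L) stop("unknown inversion: ", name)
  .junctionModelsForArm(catalog, inv$arm)[[name]]
}

## Diagnostic models for every inversion on an arm (one state-graph pass).
.junctionModelsForArm <- function(catalog, arm) {
  g <- .armStateGraph(catalog, arm)
  map <- g$map
  nodePairs <- lapply(g$perms, function(p) {
    ja <- junctionAdjacencies(p, map)
    unique(paste(pmin(ja$anchorLeft, ja$anchorRight),
                 pmax(ja$anchorLeft, ja$anchorRight), sep = "\r"))
  })
  out <- lapply(g$invNames, function(nm) {
    invSel <- as.logical(g$states[, nm])
    pInv <- unique(unlist(nodePairs[invSel]))
    pStd <- unique(unlist(nodePairs[!invSel]))
    toMat <- function(keys) {
      if (!length(keys)) return(matrix(character(), 0L, 2L))
      do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    }
    list(standard = toMat(setdiff(pStd, pInv)),
         inverted = toMat(setdiff(pInv, pStd)))
  })
  names(out) <- g$invNames
  out
}

#' Infer arrangement states from breakpoint-flanking gene adjacencies
#'
#' Compares each species' observed gene adjacencies with the junction models
#' of every catalogued inversion.  Gene identifiers are resolved through an
#' ortholog table and the catalog's anchor aliases.  Only observations on a
#' single scaffold count as adjacencies; anchors found on different
#' scaffolds leave the state unresolved (and such species never contribute
#' to ancestry voting).  If adjacencies match both arrangement models the
#' call is flagged as a conflict.
#'
#' @param observations data.frame with columns `species`, `geneA`, `geneB`,
#'   `sameScaffold` (logical) and optionally `distance`.
#' @param catalog an [InversionCatalog-class].
#' @param orthologs optional two-column data.frame (`id`, `anchor`) mapping
#'   species gene ids to catalog anchors.
#' @return data.frame with one row per species x inversion: `state`
#'   (`inverted`/`standard`/`unresolved`), `conflict`, `nInverted`,
#'   `nStandard`, `nOffScaffold`.
#' @export
inferArrangementState <- function(observations, catalog, orthologs = NULL) {
  obs <- observations
  mapId <- function(ids) {
    if (!is.null(orthologs)) {
      hit <- match(ids, orthologs$id)
      ids[!is.na(hit)] <- orthologs$anchor[hit[!is.na(hit)]]
    }
    .resolveAnchors(ids, catalog)
  }
  obs$geneA <- mapId(obs$geneA)
  obs$geneB <- mapId(obs$geneB)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  models <- unlist(lapply(catalogArms(catalog), function(a)
    .junctionModelsForArm(catalog, a)), recursive = FALSE)
  out <- NULL
  for (sp in unique(obs$species)) {
    o <- obs[obs$species == sp, , drop = FALSE]
    adj <- key(o$geneA[o$sameScaffold], o$geneB[o$sameScaffold])
    off <- key(o$geneA[!o$sameScaffold], o$geneB[!o$sameScaffold])
    for (nm in catalog@inversions$name) {
      jm <- models[[nm]]
      invKeys <- if (nrow(jm$inverted)) key(jm$inverted[, 1L], jm$inverted[, 2L]) else character(0)
      stdKeys <- if (nrow(jm$standard)) key(jm$standard[, 1L], jm$standard[, 2L]) else character(0)
      nInv <- sum(adj %in% invKeys)
      nStd <- sum(adj %in% stdKeys)
      nOff <- sum(off %in% c(invKeys, stdKeys))
      if (nInv == 0L && nStd == 0L && nOff == 0L &&
          !any(c(o$geneA, o$geneB) %in% c(jm$inverted, jm$standard)))
        next   # species carries no evidence about this inversion
      conflict <- nInv > 0L && nStd > 0L
      state <- if (conflict) "unresolved"
               else if (nInv > 0L) "inverted"
               else if (nStd > 0L) "standard"
               else "unresolved"
      out <- rbind(out, data.frame(
        species = sp, inversion = nm, state = state, conflict = conflict,
        nInverted = nInv, nStandard = nStd, nOffScaffold = nOff,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(species = character(), inversion = character(),
                      state = character(), conflict = logical(),
                      nInverted = integer(), nStandard = integer(),
                      nOffScaffold = integer(), stringsAsFactors = FALSE)
  out
}

#' Ancestral-state vote across outgroup species
#'
#' Majority vote over resolved species calls; unresolved species are
#' excluded.
#'
#' @param calls output of [inferArrangementState].
#' @return data.frame per inversion: `ancestral` state (`inverted`,
#'   `standard`, `tie` or `unresolved`), vote counts.
#' @export
ancestryVote <- function(calls) {
  out <- NULL
  for (nm in unique(calls$inversion)) {
    cc <- calls[calls$inversion == nm & calls$state != "unresolved", , drop = FALSE]
    nInv <- sum(cc$state == "inverted")
    nStd <- sum(cc$state == "standard")
    anc <- if (nInv + nStd == 0L) "unresolved"
           else if (nInv > nStd) "inverted"
           else if (nStd > nInv) "standard" else "tie"
    out <- rbind(out, data.frame(inversion = nm, ancestral = anc,
                                 nInverted = nInv, nStandard = nStd,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Length of a breakpoint region from printed coordinates
#'
#' Printed assembly coordinates are 1-based inclusive (VectorBase
#' convention), so a span `start..end` covers `end - start + 1` bp.
#'
#' @param start,end 1-based inclusive coordinates.
#' @return Length in bp.
#' @export
regionLength <- function(start, end) {
  if (any(start > end)) stop("start must be <= end")
  end - start + 1
}

#' Convert 1-based inclusive coordinates to 0-based half-open
#' @param start,end 1-based inclusive coordinates.
#' @return data.frame with `start0`, `end0` (half-open).
#' @export
coords1to0 <- function(start, end) data.frame(start0 = start - 1, end0 = end)

#' Convert 0-based half-open coordinates to 1-based inclusive
#' @param start0,end0 0-based half-open coordinates.
#' @return data.frame with `start`, `end` (1-based inclusive).
#' @export
coords0to1 <- function(start0, end0) data.frame(start = start0 + 1, end = end0)

#' Fold ratio of two breakpoint-region sizes
#'
#' @param a,b region lengths in bp (both positive).
#' @return `a / b` rounded to one decimal, as reported.
#' @export
compareRegionSizes <- function(a, b) {
  if (any(c(a, b) <= 0)) stop("region lengths must be positive")
  round(a / b, 1)
}

#' Find repeat copies of a candidate sequence in a genome
#'
#' Seeded exact local matching: every maximal exact match between the
#' candidate and the genome (both strands) of at least `minLength` bp is
#' reported, overlapping same-strand matches reduced to the longest.  The
#' synthetic genomes this operates on are error-free, so exact maximal
#' matches realise the identity threshold (`minIdentity` filters reported
#' matches, all of identity 1).
#'
#' @param candidate query sequence ([Biostrings::DNAString]).
#' @param genome subject genome ([Biostrings::DNAString]).
#' @param minLength minimum copy length in bp.
#' @param minIdentity minimum identity of reported copies.
#' @param seedLength seed width in bp.
#' @return [GenomicRanges::GRanges] of copies with strand and metadata
#'   `candStart`, `identity`.
#' @export
findRepeatCopies <- function(candidate, genome, minLength = 100L,
                             minIdentity = 0.9, seedLength = 20L) {
  if (length(candidate) >= length(genome)) stop("candidate must be shorter than genome")
  w <- seedLength
  nc <- length(candidate) - w + 1L
  if (nc < 1L) return(GenomicRanges::GRanges())
  seeds <- Biostrings::DNAStringSet(
    Biostrings::Views(candidate, start = seq_len(nc), width = w))
  pd <- Biostrings::PDict(seeds)
  L <- length(genome)
  res <- NULL
  for (str in c("+", "-")) {
    subject <- if (str == "+") genome else Biostrings::reverseComplement(genome)
    m <- Biostrings::matchPDict(pd, subject)
    si <- Biostrings::startIndex(m)
    candPos <- rep.int(seq_len(nc), lengths(si))
    genoPos <- unlist(si, use.names = FALSE)
    if (!length(genoPos)) next
    diag <- genoPos - candPos
    o <- order(diag, candPos)
    candPos <- candPos[o]; genoPos <- genoPos[o]; diag <- diag[o]
    # merge runs of consecutive seeds on the same diagonal = maximal exact
    # matches of length >= seedLength
    newRun <- c(TRUE, diff(diag) != 0L | diff(candPos) != 1L)
    runId <- cumsum(newRun)
    for (rid in unique(runId)) {
      ii <- which(runId == rid)
      len <- length(ii) + w - 1L
      if (len < minLength || 1 < minIdentity) next
      gs <- genoPos[ii[1L]]           # on `subject` coordinates
      ge <- gs + len - 1L
      if (str == "-") {
        gs2 <- L - ge + 1L
        ge <- L - gs + 1L
        gs <- gs2
      }
      res <- rbind(res, data.frame(start = gs, end = ge, strand = str,
                                   candStart = candPos[ii[1L]], len = len))
    }
  }
  if (is.null(res)) return(GenomicRanges::GRanges())
  res <- res[order(res$start, -res$len), , drop = FALSE]
  keep <- rep(TRUE, nrow(res))
  lastEnd <- -1L
  for (i in seq_len(nrow(res))) {
    if (res$start[i] <= lastEnd) keep[i] <- FALSE
    else lastEnd <- res$end[i]
  }
  res <- res[keep, , drop = FALSE]
  gr <- GenomicRanges::GRanges("genome",
    IRanges::IRanges(start = res$start, end = res$end), strand = res$strand)
  gr$candStart <- res$candStart
  gr$identity <- 1
  gr
}

#' Define element boundaries and target-site duplication from repeat copies
#'
#' Implements the element-boundary procedure: every copy is extracted with
#' `flank` bp of flanking sequence (reverse-complemented for minus-strand
#' copies) and the windows are stacked into a column profile anchored on the
#' shared repeat core (the copies' diagonal against the discovery candidate,
#' i.e. the exact-alignment special case of a flank alignment -- the
#' synthetic copies carry no indels).  The element is the maximal run of
#' columns whose mean pairwise identity over a sliding `window`-bp window
#' stays at or above `identityCutoff`; the flanks collapse into unrelated
#' sequence outside the run.  Per-copy boundaries are then fixed by locating
#' the defined consensus within each window.  The target-site duplication is
#' the maximal direct repeat (up to `tsdMax` bp) immediately flanking both
#' termini of each copy, aggregated across copies by majority vote with ties
#' resolved toward the shorter length.
#'
#' @param genome host genome ([Biostrings::DNAString]).
#' @param copies copy coordinates ([GenomicRanges::GRanges], e.g. from
#'   [findRepeatCopies]; a `candStart` metadata column, if present, anchors
#'   the profile).
#' @param flank flanking length in bp.
#' @param window sliding window for column identity.
#' @param identityCutoff mean pairwise identity threshold.
#' @param tsdMax maximal TSD length searched.
#' @param name element name for the model.
#' @return A [MITEModel-class].
#' @export
defineElementBoundaries <- function(genome, copies, flank = 1000L,
                                    window = 10L, identityCutoff = 0.5,
                                    tsdMax = 20L, name = "element") {
  if (length(copies) < 2L) stop("at least 2 copies are required")
  L <- length(genome)
  ws <- pmax(GenomicRanges::start(copies) - flank, 1L)
  we <- pmin(GenomicRanges::end(copies) + flank, L)
  wins <- lapply(seq_along(copies), function(i) {
    s <- Biostrings::subseq(genome, ws[i], we[i])
    if (as.character(GenomicRanges::strand(copies[i])) == "-")
      s <- Biostrings::reverseComplement(s)
    s
  })
  nco <- length(wins)
  # anchor column of each copy: the copy's offset on the shared core
  anchor <- if (!is.null(copies$candStart)) copies$candStart else rep(1L, nco)
  # window position of the copy (match) start, in oriented coordinates
  qstart <- ifelse(as.character(GenomicRanges::strand(copies)) == "-",
                   we - GenomicRanges::end(copies) + 1L,
                   GenomicRanges::start(copies) - ws + 1L)
  # column c corresponds, in row i, to window position qstart[i] + (c - c0[i])
  c0 <- flank + anchor       # column of each copy's match start
  offset <- c0 - qstart      # window pos = col - offset
  W <- max(we - ws + 1L + offset)
  chars <- matrix("-", nco, W)
  ppos <- matrix(NA_integer_, nco, W)
  for (i in seq_len(nco)) {
    wchr <- strsplit(as.character(wins[[i]]), "")[[1L]]
    cols <- seq_along(wchr) + offset[i]
    keep <- cols >= 1L & cols <= W
    chars[i, cols[keep]] <- wchr[keep]
    ppos[i, cols[keep]] <- seq_along(wchr)[keep]
  }
  # mean pairwise identity per column (gaps count as mismatches)
  colIdent <- vapply(seq_len(W), function(j) {
    cc <- chars[, j]
    cc2 <- cc[cc != "-"]
    npair <- nco * (nco - 1) / 2
    if (length(cc2) < 2L) return(0)
    tt <- table(cc2)
    sum(tt * (tt - 1) / 2) / npair
  }, 0)
  sm10 <- stats::filter(colIdent, rep(1 / window, window), sides = 2)
  sm10[is.na(sm10)] <- 0
  core <- as.numeric(sm10) >= identityCutoff
  if (!any(core)) stop("no conserved core found")
  runs <- rle(core)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- which(runs$values)
  big <- ok[which.max(runs$lengths[ok])]
  c5 <- starts[big]; c3 <- ends[big]
  # trim to exact columns: step inward while column identity is weak
  while (c5 < c3 && colIdent[c5] < identityCutoff) c5 <- c5 + 1L
  while (c3 > c5 && colIdent[c3] < identityCutoff) c3 <- c3 - 1L

  consensus <- paste(vapply(c5:c3, function(j) {
    cc <- chars[, j]; cc <- cc[cc != "-"]
    names(sort(table(cc), decreasing = TRUE))[1L]
  }, ""), collapse = "")

  # per-copy boundaries (window coordinates): locate the defined consensus
  # in each copy's window (exact for non-degenerate copies), falling back to
  # the aligned columns; then TSD from the oriented window flanks
  consDNA <- Biostrings::DNAString(consensus)
  nearestPos <- function(i, col, dir) {
    j <- col
    while (j >= 1L && j <= W && is.na(ppos[i, j])) j <- j + dir
    ppos[i, j]
  }
  tsdLens <- integer(nco)
  bnd <- matrix(NA_integer_, nco, 2L)
  for (i in seq_len(nco)) {
    hit <- Biostrings::matchPattern(consDNA, wins[[i]])
    if (length(hit) == 1L) {
      p5 <- Biostrings::start(hit); p3 <- Biostrings::end(hit)
    } else {
      p5 <- nearestPos(i, c5, 1L)
      p3 <- nearestPos(i, c3, -1L)
    }
    bnd[i, ] <- c(p5, p3)
    wchr <- strsplit(as.character(wins[[i]]), "")[[1L]]
    upLen <- min(tsdMax, p5 - 1L)
    dnLen <- min(tsdMax, length(wchr) - p3)
    up <- wchr[seq.int(p5 - upLen, length.out = upLen)]
    dn <- wchr[seq.int(p3 + 1L, length.out = dnLen)]
    tl <- 0L
    for (Lt in seq_len(min(upLen, dnLen))) {
      if (identical(up[seq.int(upLen - Lt + 1L, upLen)], dn[seq_len(Lt)]))
        tl <- Lt
    }
    tsdLens[i] <- tl
  }
  tt <- sort(table(tsdLens), decreasing = TRUE)
  best <- as.integer(names(tt)[tt == max(tt)])
  tsd <- min(best)   # ties toward the shorter duplication

  # map window boundaries back to genome coordinates
  gs <- integer(nco); ge <- integer(nco)
  for (i in seq_len(nco)) {
    if (as.character(GenomicRanges::strand(copies[i])) == "+") {
      gs[i] <- ws[i] + bnd[i, 1L] - 1L
      ge[i] <- ws[i] + bnd[i, 2L] - 1L
    } else {
      wlen <- we[i] - ws[i] + 1L
      gs[i] <- ws[i] + (wlen - bnd[i, 2L])
      ge[i] <- ws[i] + (wlen - bnd[i, 1L])
    }
  }
  out <- GenomicRanges::GRanges("genome", IRanges::IRanges(start = gs, end = ge),
                                strand = GenomicRanges::strand(copies))
  new("MITEModel", name = name, consensus = Biostrings::DNAString(consensus),
      tsdLength = as.integer(tsd), copies = out)
}

#' Discover and model a repeat element around a candidate region
#'
#' Convenience wrapper chaining [findRepeatCopies] and
#' [defineElementBoundaries], mirroring the candidate-query procedure used
#' to characterise novel elements at inversion breakpoints.
#'
#' @param candidate candidate region sequence containing the element.
#' @param genome host genome.
#' @param minLength,minIdentity,seedLength copy-search parameters.
#' @param flank,window,identityCutoff,tsdMax,name boundary parameters.
#' @return A [MITEModel-class].
#' @export
modelElement <- function(candidate, genome, minLength = 100L,
                         minIdentity = 0.9, seedLength = 20L, flank = 1000L,
                         window = 10L, identityCutoff = 0.5, tsdMax = 20L,
                         name = "element") {
  copies <- findRepeatCopies(candidate, genome, minLength = minLength,
                             minIdentity = minIdentity, seedLength = seedLength)
  if (length(copies) < 2L) stop("fewer than 2 repeat copies found")
  defineElementBoundaries(genome, copies, flank = flank, window = window,
                          identityCutoff = identityCutoff, tsdMax = tsdMax,
                          name = name)
}
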