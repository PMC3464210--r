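## Run expr with a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) stop("seed is mandatory")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

.randomDNA <- function(n) {
  Biostrings::DNAString(paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = ""))
}

#' Simulate an ancestral genome with gene annotations
#'
#' A uniform-random DNA sequence with non-overlapping gene intervals placed
#' on both strands.  Deterministic under the seed.
#'
#' @param genomeLength genome length in bp.
#' @param nGenes number of genes.
#' @param geneLength gene length in bp (fixed).
#' @param seed RNG seed (mandatory).
#' @return list with `genome` ([Biostrings::DNAString]) and `genes`
#'   ([GenomicRanges::GRanges] with strand and `name`).
#' @export
simulateAncestralGenome <- function(genomeLength, nGenes = 100L,
                                    geneLength = 500L, seed) {
  .withSeed(seed, {
    slots <- floor(genomeLength / (geneLength + 1L))
    if (nGenes > slots)
      stop("genes cannot fit: ", nGenes, " genes of ", geneLength,
           " bp in ", genomeLength, " bp")
    genome <- .randomDNA(genomeLength)
    if (nGenes > 0L) {
      starts <- sort(sample(slots, nGenes)) * (geneLength + 1L) - geneLength
      genes <- GenomicRanges::GRanges("genome",
        IRanges::IRanges(start = starts, width = geneLength),
        strand = sample(c("+", "-"), nGenes, replace = TRUE))
      genes$name <- sprintf("gene%04d", seq_len(nGenes))
    } else {
      genes <- GenomicRanges::GRanges()
    }
    list(genome = genome, genes = genes)
  })
}

#' Realize an inversion catalog on synthetic chromosome arms
#'
#' Generates one random reference sequence per arm and maps the catalog's
#' breakpoint ordering keys to genomic coordinates (evenly spread over the
#' central 80% of the arm, preserving order).  A unique marker 36-mer is
#' recorded at the midpoint of every segment so that segment order and
#' orientation can be recovered from rearranged genomes, and anchor "genes"
#' (unique 36-mers) are placed immediately flanking every breakpoint.
#'
#' @param catalog an [InversionCatalog-class].
#' @param armLength arm length in bp (single value or named per arm).
#' @param seed RNG seed.
#' @return list with `arms` (named [Biostrings::DNAStringSet]), `coords`
#'   (named list of breakpoint coordinate vectors), `segTags` (named list of
#'   per-segment marker [Biostrings::DNAStringSet]), `anchors` (data.frame of
#'   anchor placements).
#' @export
realizeCatalog <- function(catalog, armLength = 100000L, seed) {
  arms <- catalogArms(catalog)
  if (length(armLength) == 1L) armLength <- setNames(rep(armLength, length(arms)), arms)
  .withSeed(seed, {
    seqs <- list(); coords <- list(); segTags <- list(); anchors <- NULL
    for (arm in arms) {
      L <- as.integer(armLength[[arm]])
      map <- buildSegmentMap(catalog, arm)
      s <- Biostrings::DNAString(paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""))
      nb <- length(map@breakpoints)
      co <- round(seq(0.1, 0.9, length.out = max(nb, 1L)) * L)[seq_len(nb)]
      bounds <- c(0L, co, L)        # 0-based segment bounds
      tags <- character(map@n)
      for (k in seq_len(map@n)) {
        mid <- floor((bounds[k] + bounds[k + 1L]) / 2L)
        tags[k] <- as.character(Biostrings::subseq(s, mid + 1L, mid + 36L))
      }
      # anchor genes flanking each breakpoint (36-mers just inside segments)
      anch <- .segmentAnchors(map)
      for (j in seq_len(nb)) {
        anchors <- rbind(anchors, data.frame(
          arm = arm,
          anchor = c(map@junctionTel[j], map@junctionCen[j]),
          start0 = c(co[j] - 60L, co[j] + 24L),
          stringsAsFactors = FALSE))
      }
      seqs[[arm]] <- s
      coords[[arm]] <- co
      st <- Biostrings::DNAStringSet(tags)
      names(st) <- paste0(arm, ".S", seq_len(map@n))
      segTags[[arm]] <- st
    }
    list(arms = Biostrings::DNAStringSet(unlist(lapply(seqs, as.character))),
         coords = coords, segTags = segTags, anchors = anchors)
  })
}

## Assemble an arm sequence from a signed permutation over reference
## segments, inserting novel sequence of length `gap` at derived junctions.
.assembleArm <- function(refSeq, coords, perm, gap = 0L) {
  n <- length(perm)
  bounds <- c(0L, coords, length(refSeq))
  segs <- lapply(seq_len(n), function(k)
    Biostrings::subseq(refSeq, bounds[k] + 1L, bounds[k + 1L]))
  pieces <- list()
  for (i in seq_len(n)) {
    x <- perm[i]
    piece <- if (x > 0L) segs[[x]] else Biostrings::reverseComplement(segs[[-x]])
    pieces[[length(pieces) + 1L]] <- piece
    if (i < n && gap > 0L) {
      # derived junction = consecutive pair not present in the reference
      if (is.na(.pairJunction(perm[i], perm[i + 1L])))
        pieces[[length(pieces) + 1L]] <- .randomDNA(gap)
    }
  }
  do.call(Biostrings::xscat, pieces)
}

#' Evolve karyotypes along a tree
#'
#' Walks a rooted tree from an all-standard (or given) root karyotype,
#' applying the inversion events attached to each edge.  Every flip is
#' checked for trajectory validity (see [validateTrajectory]); leaf genomes
#' are the ancestral arm sequences rearranged by the leaf's signed
#' permutations, with optional novel-sequence gaps at derived junctions.
#'
#' @param realized output of [realizeCatalog].
#' @param tree rooted [ape::phylo]; `edgeEvents` is a list (parallel to the
#'   edge matrix rows) of character vectors of inversion names.
#' @param edgeEvents per-edge inversion events.
#' @param catalog the [InversionCatalog-class].
#' @param junctionGap length of novel sequence inserted at derived junctions.
#' @param rootStates optional named state vector for the root (default all
#'   standard).
#' @return list with `genomes` (per-taxon named list of arm
#'   [Biostrings::DNAString]s), `karyotypes` ([KaryotypeMatrix-class]),
#'   `perms` (per-taxon encoded permutations) and `truth` (events per edge).
#' @export
evolveKaryotypes <- function(realized, tree, edgeEvents, catalog,
                             junctionGap = 0L, rootStates = NULL) {
  arms <- catalogArms(catalog)
  maps <- lapply(arms, function(a) buildSegmentMap(catalog, a))
  names(maps) <- arms
  invArm <- setNames(catalog@inversions$arm, catalog@inversions$name)
  nt <- length(tree$tip.label)
  if (is.null(rootStates))
    rootStates <- setNames(rep("standard", nrow(catalog@inversions)),
                           catalog@inversions$name)
  nodeStates <- vector("list", nt + tree$Nnode)
  nodePerms <- vector("list", nt + tree$Nnode)
  root <- nt + 1L
  nodeStates[[root]] <- rootStates
  nodePerms[[root]] <- lapply(encodeKaryotype(rootStates, catalog), permElements)

  ord <- rev(ape::postorder(tree))   # edges, parents before children
  for (i in ord) {
    par <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
    st <- nodeStates[[par]]
    pp <- nodePerms[[par]]
    evs <- if (i <= length(edgeEvents)) edgeEvents[[i]] else character(0)
    for (nm in evs) {
      arm <- invArm[[nm]]
      q <- .flipInversion(pp[[arm]], catalog, maps[[arm]], nm, unname(st[[nm]]))
      if (is.null(q))
        stop("invalid trajectory: flip of ", nm, " on edge ", i,
             " is not permutation-contiguous")
      pp[[arm]] <- q
      st[[nm]] <- if (st[[nm]] == "standard") "inverted" else "standard"
    }
    nodeStates[[ch]] <- st
    nodePerms[[ch]] <- pp
  }

  taxa <- tree$tip.label
  states <- do.call(rbind, lapply(seq_len(nt), function(i) nodeStates[[i]]))
  rownames(states) <- taxa
  genomes <- lapply(seq_len(nt), function(i) {
    g <- lapply(arms, function(a)
      .assembleArm(realized$arms[[a]], realized$coords[[a]],
                   nodePerms[[i]][[a]], gap = junctionGap))
    names(g) <- arms
    g
  })
  names(genomes) <- taxa
  perms <- lapply(seq_len(nt), function(i) nodePerms[[i]])
  names(perms) <- taxa
  list(genomes = genomes,
       karyotypes = karyotypeMatrix(states, catalog),
       perms = perms,
       truth = list(edgeEvents = edgeEvents, rootStates = rootStates))
}

#' Recover an arm's signed permutation from a genome
#'
#' Locates each segment's unique marker 36-mer (forward or reverse
#' complement) in a rearranged arm sequence and returns the segments in
#' genomic order with orientation signs.
#'
#' @param armSeq arm sequence ([Biostrings::DNAString]).
#' @param tags per-segment marker [Biostrings::DNAStringSet] (from
#'   [realizeCatalog]).
#' @return Integer vector: the recovered signed permutation.
#' @export
recoverArmPermutation <- function(armSeq, tags) {
  hits <- lapply(seq_along(tags), function(k) {
    fw <- Biostrings::start(Biostrings::matchPattern(tags[[k]], armSeq))
    rc <- Biostrings::start(Biostrings::matchPattern(
      Biostrings::reverseComplement(tags[[k]]), armSeq))
    if (length(fw) + length(rc) != 1L)
      stop("segment marker ", names(tags)[k], " not unique in arm")
    if (length(fw)) c(pos = fw, sign = 1L) else c(pos = rc, sign = -1L)
  })
  pos <- vapply(hits, `[[`, 0, "pos")
  sgn <- vapply(hits, `[[`, 0, "sign")
  ord <- order(pos)
  as.integer(seq_along(tags)[ord] * sgn[ord])
}

#' Simulate a reference genome and a derived genome with one inversion
#'
#' Direct single-arm helper for breakpoint-detection studies: the derived
#' genome carries the reference segment `[b1, b2)` (0-based, half-open)
#' reverse-complemented, with optional novel "breakpoint region" sequence of
#' `gapLength` bp inserted at both derived junctions.
#'
#' @param genomeLength reference length in bp.
#' @param b1,b2 0-based breakpoint coordinates, `b1 < b2`.
#' @param gapLength novel-sequence length at each derived junction.
#' @param seed RNG seed.
#' @return list with `reference`, `derived` ([Biostrings::DNAString]) and
#'   `truth` (breakpoints, gap).
#' @export
simulateInversionGenome <- function(genomeLength, b1, b2, gapLength = 0L, seed) {
  stopifnot(b1 > 0, b2 > b1, b2 < genomeLength)
  .withSeed(seed, {
    ref <- .randomDNA(genomeLength)
    A <- Biostrings::subseq(ref, 1L, b1)
    B <- Biostrings::subseq(ref, b1 + 1L, b2)
    C <- Biostrings::subseq(ref, b2 + 1L, genomeLength)
    pieces <- list(A)
    if (gapLength > 0L) pieces <- c(pieces, list(.randomDNA(gapLength)))
    pieces <- c(pieces, list(Biostrings::reverseComplement(B)))
    if (gapLength > 0L) pieces <- c(pieces, list(.randomDNA(gapLength)))
    pieces <- c(pieces, list(C))
    list(reference = ref, derived = do.call(Biostrings::xscat, pieces),
         truth = list(b1 = b1, b2 = b2, gap = gapLength))
  })
}

#' Simulate a mate-pair library
#'
#' Fragments are placed uniformly on the sample genome with insert sizes
#' drawn from Normal(insertSize, insertSd), rounded and truncated to at
#' least twice the read length; the pair count is
#' `ceiling(coverage * genomeLength / (2 * readLength))`.  Under the FR
#' convention read 1 is the forward sequence at the fragment's 5' end and
#' read 2 the reverse complement of its 3' end.  Reads are error-free by
#' default; an optional uniform substitution rate is available.
#'
#' @param genome sample genome ([Biostrings::DNAString]).
#' @param lib a [LibrarySpec-class].
#' @param coverage read coverage (fold).
#' @param seed RNG seed.
#' @param errorRate per-base substitution probability (default 0).
#' @return list with `read1`, `read2` ([Biostrings::DNAStringSet], names
#'   `frag<i>/1`, `frag<i>/2`) and `truth` (data.frame of fragment start and
#'   insert size, 0-based).
#' @export
simulateMatePairLibrary <- function(genome, lib, coverage, seed, errorRate = 0) {
  L <- length(genome)
  rl <- lib@readLength
  if (lib@insertSize >= L) stop("insert exceeds genome length")
  npairs <- as.integer(ceiling(coverage * L / (2 * rl)))
  if (npairs == 0L)
    return(list(read1 = Biostrings::DNAStringSet(), read2 = Biostrings::DNAStringSet(),
                truth = data.frame(start0 = integer(), insert = integer())))
  .withSeed(seed, {
    ins <- as.integer(round(stats::rnorm(npairs, lib@insertSize, lib@insertSd)))
    ins <- pmax(ins, 2L * rl)
    ins <- pmin(ins, L)
    start <- vapply(ins, function(I) sample.int(L - I + 1L, 1L), 1L)  # 1-based
    r1 <- Biostrings::DNAStringSet(Biostrings::Views(genome, start = start, width = rl))
    r2 <- Biostrings::reverseComplement(
      Biostrings::DNAStringSet(Biostrings::Views(genome, start = start + ins - rl, width = rl)))
    if (errorRate > 0) {
      r1 <- .addSubstitutions(r1, errorRate)
      r2 <- .addSubstitutions(r2, errorRate)
    }
    ids <- sprintf("frag%07d", seq_len(npairs))
    names(r1) <- paste0(ids, "/1")
    names(r2) <- paste0(ids, "/2")
    list(read1 = r1, read2 = r2,
         truth = data.frame(start0 = start - 1L, insert = ins))
  })
}

## Uniform substitutions at rate `rate` (draws within the current RNG state).
.addSubstitutions <- function(reads, rate) {
  ch <- as.character(reads)
  total <- sum(nchar(ch))
  nmut <- stats::rbinom(1L, total, rate)
  if (nmut == 0L) return(reads)
  w <- nchar(ch[1L])
  sites <- sample(total, nmut)
  readIdx <- (sites - 1L) %/% w + 1L
  off <- (sites - 1L) %% w + 1L
  for (k in seq_len(nmut)) {
    cur <- substr(ch[readIdx[k]], off[k], off[k])
    substr(ch[readIdx[k]], off[k], off[k]) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
  }
  out <- Biostrings::DNAStringSet(ch)
  names(out) <- names(reads)
  out
}

#' Plant MITE copies with target-site duplications
#'
#' Inserts copies of a synthetic miniature inverted-repeat element at random
#' positions (random strand).  Each insertion duplicates the `tsdLength`
#' bases at its target site, so the element ends up flanked by a direct
#' repeat on both sides; the genome grows by
#' `copies * (elementLength + tsdLength)` bp.
#'
#' @param genome host genome ([Biostrings::DNAString]).
#' @param elementLength element length in bp.
#' @param tsdLength target-site-duplication length in bp.
#' @param copies number of insertions.
#' @param seed RNG seed.
#' @param tirLength terminal-inverted-repeat length of the synthetic element.
#' @param minSpacing minimum distance between insertion sites.
#' @return list with `genome` (modified [Biostrings::DNAString]), `element`
#'   (the planted consensus) and `truth` ([GenomicRanges::GRanges] of the
#'   element copies in the modified genome, with strand and `tsd`).
#' @export
plantMite <- function(genome, elementLength = 350L, tsdLength = 3L,
                      copies = 15L, seed, tirLength = 15L,
                      minSpacing = 4000L) {
  if (copies < 1L) stop("copies must be >= 1")
  if (elementLength >= length(genome)) stop("element longer than genome")
  .withSeed(seed, {
    core <- .randomDNA(elementLength - 2L * tirLength)
    tir <- .randomDNA(tirLength)
    element <- Biostrings::xscat(tir, core, Biostrings::reverseComplement(tir))
    L <- length(genome)
    lo <- tsdLength + 2000L
    hi <- L - 2000L
    # spaced sites drawn directly: sorted uniforms plus cumulative spacing
    span <- hi - lo - (copies - 1L) * minSpacing
    if (span < copies)
      stop("cannot fit ", copies, " insertion sites ", minSpacing,
           " bp apart in ", L, " bp")
    sites <- lo + sort(sample.int(span, copies)) - 1L +
      (seq_len(copies) - 1L) * minSpacing
    sites <- sort(sites, decreasing = TRUE)   # insert right-to-left
    g <- as.character(genome)
    strands <- sample(c("+", "-"), copies, replace = TRUE)
    rec <- data.frame(site = sites, strand = strands)
    for (k in seq_len(copies)) {
      s <- sites[k]   # insert after position s + tsdLength, duplicating (s+1)..(s+tsdLength)
      el <- if (strands[k] == "+") as.character(element)
            else as.character(Biostrings::reverseComplement(element))
      tsd <- if (tsdLength > 0L) substr(g, s + 1L, s + tsdLength) else ""
      g <- paste0(substr(g, 1L, s + tsdLength), el, substr(g, s + 1L, nchar(g)))
    }
    # final coordinates: recompute left-to-right (insertions to the right of a
    # site do not move it; we inserted right-to-left so earlier sites shifted
    # by later-inserted elements to their left -- none, by construction)
    rec <- rec[order(rec$site), ]
    shift <- (seq_len(copies) - 1L) * (elementLength + tsdLength)
    starts <- rec$site + tsdLength + shift + 1L
    tr <- GenomicRanges::GRanges("genome",
      IRanges::IRanges(start = starts, width = elementLength),
      strand = rec$strand)
    tr$tsd <- tsdLength
    list(genome = Biostrings::DNAString(g), element = element, truth = tr)
  })
}
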