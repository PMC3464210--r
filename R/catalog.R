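#' Construct an inversion catalog
#'
#' @param inversions data.frame with columns `name`, `arm`, `bpDistal`,
#'   `bpProximal`, `anchorDistalTel`, `anchorDistalCen`,
#'   `anchorProximalTel`, `anchorProximalCen`.
#' @param anchorAliases optional data.frame (`alias`, `anchor`) of
#'   alternative anchor names.
#' @param description free-text label.
#' @return An [InversionCatalog-class].
#' @export
inversionCatalog <- function(inversions,
                             anchorAliases = data.frame(alias = character(),
                                                        anchor = character()),
                             description = "custom catalog") {
  inversions <- as.data.frame(inversions, stringsAsFactors = FALSE)
  new("InversionCatalog", inversions = inversions,
      anchorAliases = as.data.frame(anchorAliases), description = description)
}

#' The fixed-inversion catalog of the Anopheles gambiae complex
#'
#' Ten fixed paracentric inversions: five on the X (Xa, Xg, Xb, Xc, Xd),
#' three on 2R (2Ro, 2Rp, 2Rm), one on 2L (2La) and one on 3L (3La).
#' 2Ro and 2Rp overlap; their breakpoint anchors are the AgamP3 genes flanking
#' the cytologically and molecularly mapped breakpoints (2Ro distal between
#' AGAP001760 and AGAP001762, proximal between AGAP002933 and AGAP002935;
#' 2Rp distal between AGAP001983 and AGAP001984, proximal between AGAP003327
#' and AGAP003328).  AGAP013533 is registered as an alias for the
#' AGAP001983-side block of the distal 2Rp breakpoint.  The X inversions are
#' modelled as mutually non-overlapping intervals with distinct breakpoints;
#' 2Rm, whose breakpoint genes are not molecularly characterised, is placed
#' proximal to 2Rp and non-overlapping, with synthetic anchors.
#'
#' Breakpoint positions on 2R and 2L are the approximate AgamP3 megabase
#' coordinates (9.48 / 29.84 Mb for 2Ro; 20.52 / 42.16 Mb for 2La); positions
#' on the other arms are ordering keys only.
#'
#' @return An [InversionCatalog-class].
#' @export
gambiaeComplexCatalog <- function() {
  syn <- function(name) paste0("g", sub("^[0-9]*", "", name), c("D1", "D2", "P1", "P2"))
  xrow <- function(name, bp1, bp2) {
    a <- syn(name)
    data.frame(name = name, arm = "X", bpDistal = bp1, bpProximal = bp2,
               anchorDistalTel = a[1], anchorDistalCen = a[2],
               anchorProximalTel = a[3], anchorProximalCen = a[4],
               stringsAsFactors = FALSE)
  }
  m <- syn("2Rm"); l3 <- syn("3La")
  inv <- rbind(
    xrow("Xa", 1, 2), xrow("Xg", 3, 4), xrow("Xb", 5, 6),
    xrow("Xc", 7, 8), xrow("Xd", 9, 10),
    data.frame(name = "2Ro", arm = "2R", bpDistal = 9.48, bpProximal = 29.84,
               anchorDistalTel = "AGAP001760", anchorDistalCen = "AGAP001762",
               anchorProximalTel = "AGAP002933", anchorProximalCen = "AGAP002935",
               stringsAsFactors = FALSE),
    data.frame(name = "2Rp", arm = "2R", bpDistal = 11.00, bpProximal = 33.00,
               anchorDistalTel = "AGAP001983", anchorDistalCen = "AGAP001984",
               anchorProximalTel = "AGAP003327", anchorProximalCen = "AGAP003328",
               stringsAsFactors = FALSE),
    data.frame(name = "2Rm", arm = "2R", bpDistal = 40.00, bpProximal = 44.00,
               anchorDistalTel = m[1], anchorDistalCen = m[2],
               anchorProximalTel = m[3], anchorProximalCen = m[4],
               stringsAsFactors = FALSE),
    # 2La anchors: the pairs (AGAP007068, AGAP005778) and (AGAP007069,
    # AGAP005780) are adjacent in the *inverted* (2La) arrangement, the one
    # whose orthologs are syntenic in Culex/Aedes; the standard-frame
    # junctions are therefore (7068, 7069) and (5778, 5780)
    data.frame(name = "2La", arm = "2L", bpDistal = 20.52, bpProximal = 42.16,
               anchorDistalTel = "AGAP007068", anchorDistalCen = "AGAP007069",
               anchorProximalTel = "AGAP005778", anchorProximalCen = "AGAP005780",
               stringsAsFactors = FALSE),
    data.frame(name = "3La", arm = "3L", bpDistal = 12, bpProximal = 30,
               anchorDistalTel = l3[1], anchorDistalCen = l3[2],
               anchorProximalTel = l3[3], anchorProximalCen = l3[4],
               stringsAsFactors = FALSE)
  )
  inversionCatalog(inv,
    anchorAliases = data.frame(alias = "AGAP013533", anchor = "AGAP001983",
                               stringsAsFactors = FALSE),
    description = "An. gambiae complex (10 fixed paracentric inversions)")
}

#' The two-inversion 2R catalog (2Ro and 2Rp only)
#'
#' The overlapping 2Ro/2Rp pair on 2R in isolation, yielding the five-segment
#' 2R map delimited by the four mapped breakpoints.
#'
#' @return An [InversionCatalog-class].
#' @export
catalog2Rop <- function() {
  cat <- gambiaeComplexCatalog()
  subsetCatalog(cat, c("2Ro", "2Rp"))
}

#' Subset a catalog to selected inversions
#'
#' @param catalog an [InversionCatalog-class].
#' @param names inversion names to keep.
#' @return An [InversionCatalog-class].
#' @export
subsetCatalog <- function(catalog, names) {
  stopifnot(all(names %in% catalog@inversions$name))
  inv <- catalog@inversions[match(names, catalog@inversions$name), , drop = FALSE]
  rownames(inv) <- NULL
  inversionCatalog(inv, catalog@anchorAliases,
                   paste0(catalog@description, " [", paste(names, collapse = ","), "]"))
}

#' Arms covered by a catalog
#' @param catalog an [InversionCatalog-class].
#' @return Character vector of arm identifiers.
#' @export
catalogArms <- function(catalog) unique(catalog@inversions$arm)

#' Inversion definitions of a catalog
#' @param catalog an [InversionCatalog-class].
#' @return The inversion data.frame.
#' @export
catalogInversions <- function(catalog) catalog@inversions

#' Build the segment map of one arm
#'
#' Collects the distinct breakpoints that the catalog places on `arm`,
#' orders them telomere to centromere, and returns the resulting partition
#' into segments with the anchor pair at every internal junction.  `n`
#' distinct breakpoints give `n + 1` segments; an arm without catalogued
#' inversions is a single segment.
#'
#' @param catalog an [InversionCatalog-class].
#' @param arm arm identifier.
#' @return A [SegmentMap-class].
#' @export
buildSegmentMap <- function(catalog, arm) {
  inv <- catalog@inversions[catalog@inversions$arm == arm, , drop = FALSE]
  bp <- c(inv$bpDistal, inv$bpProximal)
  tel <- c(inv$anchorDistalTel, inv$anchorProximalTel)
  cen <- c(inv$anchorDistalCen, inv$anchorProximalCen)
  if (anyDuplicated(bp)) stop("unordered breakpoints on arm ", arm)
  o <- order(bp)
  new("SegmentMap", arm = arm, breakpoints = bp[o],
      junctionTel = tel[o], junctionCen = cen[o],
      n = length(bp) + 1L)
}

#' Segment maps for every arm of a catalog
#' @param catalog an [InversionCatalog-class].
#' @return Named list of [SegmentMap-class] objects.
#' @export
buildSegmentMaps <- function(catalog) {
  arms <- catalogArms(catalog)
  maps <- lapply(arms, function(a) buildSegmentMap(catalog, a))
  names(maps) <- arms
  maps
}

## Segment end anchors in the reference orientation: left (telomeric) and
## right (centromeric) anchor of each segment, with synthetic terminal labels.
.segmentAnchors <- function(map) {
  n <- map@n
  left <- c(paste0(map@arm, ":tel"), map@junctionCen)
  right <- c(map@junctionTel, paste0(map@arm, ":cen"))
  data.frame(segment = seq_len(n), left = left, right = right,
             stringsAsFactors = FALSE)
}

## Junction indices (1..n-1) of an inversion on its arm's map, derived from
## breakpoint positions: the inversion spans segments (jDistal+1)..jProximal.
.inversionJunctions <- function(catalog, map, name) {
  inv <- catalog@inversions[catalog@inversions$name == name, , drop = FALSE]
  if (nrow(inv) != 1L) stop("unknown inversion: ", name)
  j1 <- match(inv$bpDistal, map@breakpoints)
  j2 <- match(inv$bpProximal, map@breakpoints)
  if (is.na(j1) || is.na(j2)) stop("inversion ", name, " breakpoints not on map")
  c(distal = j1, proximal = j2)
}

#' Segment interval of an inversion
#'
#' @param catalog an [InversionCatalog-class].
#' @param name inversion name.
#' @param map optional pre-built [SegmentMap-class] of the inversion's arm.
#' @return Integer vector `c(from, to)`: the segments the inversion spans in
#'   the reference frame.
#' @export
inversionInterval <- function(catalog, name, map = NULL) {
  arm <- catalog@inversions$arm[catalog@inversions$name == name]
  if (is.null(map)) map <- buildSegmentMap(catalog, arm)
  j <- .inversionJunctions(catalog, map, name)
  c(from = unname(j[1]) + 1L, to = unname(j[2]))
}

## Resolve anchor aliases to canonical anchor ids.
.resolveAnchors <- function(ids, catalog) {
  al <- catalog@anchorAliases
  if (nrow(al)) {
    hit <- match(ids, al$alias)
    ids[!is.na(hit)] <- al$anchor[hit[!is.na(hit)]]
  }
  ids
}
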