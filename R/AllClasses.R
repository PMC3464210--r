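#' @import methods
#' @importFrom S4Vectors isSingleString
NULL

#' Catalog of fixed paracentric inversions
#'
#' An `InversionCatalog` holds the fixed inversions of a species complex:
#' for each inversion its chromosome arm, the positions of its distal and
#' proximal breakpoints along the arm (telomere to centromere), and the pair
#' of flanking gene anchors at each breakpoint.  Breakpoint positions are
#' abstract ordering keys (they double as genomic coordinates when the
#' catalog is realised on a synthetic genome).
#'
#' @slot inversions data.frame with one row per inversion: `name`, `arm`,
#'   `bpDistal`, `bpProximal` (numeric positions, distal < proximal),
#'   `anchorDistalTel`, `anchorDistalCen`, `anchorProximalTel`,
#'   `anchorProximalCen` (gene anchor identifiers; the *Tel* gene sits on the
#'   telomeric side of the breakpoint).
#' @slot anchorAliases data.frame (`alias`, `anchor`) of alternative anchor
#'   identifiers resolving to a catalogued anchor.
#' @slot description free-text label.
#' @exportClass InversionCatalog
setClass("InversionCatalog",
  representation(
    inversions = "data.frame",
    anchorAliases = "data.frame",
    description = "character"
  )
)

setValidity("InversionCatalog", function(object) {
  inv <- object@inversions
  need <- c("name", "arm", "bpDistal", "bpProximal",
            "anchorDistalTel", "anchorDistalCen",
            "anchorProximalTel", "anchorProximalCen")
  if (!all(need %in% names(inv)))
    return(paste("inversions must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(inv$name)) return("inversion names must be unique")
  if (any(inv$bpDistal >= inv$bpProximal))
    return("each inversion must satisfy distal breakpoint < proximal breakpoint")
  for (arm in unique(inv$arm)) {
    bp <- c(inv$bpDistal[inv$arm == arm], inv$bpProximal[inv$arm == arm])
    if (anyDuplicated(bp))
      return(sprintf("unordered breakpoints: duplicated breakpoint position on arm %s", arm))
  }
  TRUE
})

#' Segment map of a chromosome arm
#'
#' Segments are the regions between consecutive catalogued breakpoints on one
#' arm, ordered telomere to centromere.  `n` distinct breakpoints yield
#' `n + 1` segments.  Each internal junction carries the pair of gene anchors
#' flanking it in the reference (all-standard) arrangement.
#'
#' @slot arm arm identifier.
#' @slot breakpoints sorted breakpoint positions.
#' @slot junctionTel,junctionCen anchor on the telomeric / centromeric side
#'   of each junction (parallel to `breakpoints`).
#' @slot n number of segments.
#' @exportClass SegmentMap
setClass("SegmentMap",
  representation(
    arm = "character",
    breakpoints = "numeric",
    junctionTel = "character",
    junctionCen = "character",
    n = "integer"
  )
)

setValidity("SegmentMap", function(object) {
  if (is.unsorted(object@breakpoints, strictly = TRUE) && length(object@breakpoints) > 1)
    return("breakpoints must be strictly increasing")
  if (object@n != length(object@breakpoints) + 1L)
    return("n must equal number of breakpoints + 1")
  if (length(object@junctionTel) != length(object@breakpoints) ||
      length(object@junctionCen) != length(object@breakpoints))
    return("junction anchors must parallel breakpoints")
  TRUE
})

#' Signed permutation of arm segments
#'
#' One chromosome arm's segment order and orientation relative to the
#' reference (all-standard) arrangement, in which the permutation is the
#' identity.  A negative element is a segment in reversed orientation.
#'
#' @slot arm arm identifier.
#' @slot elements integer vector; absolute values are a permutation of
#'   `1..n`, signs give orientation.
#' @exportClass SignedPermutation
setClass("SignedPermutation",
  representation(arm = "character", elements = "integer")
)

setValidity("SignedPermutation", function(object) {
  e <- object@elements
  if (any(e == 0L)) return("elements must be non-zero")
  if (!identical(sort(abs(e)), seq_along(e))) return("absolute values must be a permutation of 1..n")
  TRUE
})

#' Karyotype matrix of arrangement states
#'
#' Taxa by inversion matrix of arrangement states (`"standard"` or
#' `"inverted"`, `NA` for unknown), together with the catalog the states
#' refer to and, optionally, the designated outgroup taxon.
#'
#' @slot states character matrix, rows = taxa, columns = inversion names.
#' @slot outgroup outgroup taxon label (`character(0)` if none).
#' @slot catalog the [InversionCatalog-class] the columns refer to.
#' @exportClass KaryotypeMatrix
setClass("KaryotypeMatrix",
  representation(
    states = "matrix",
    outgroup = "character",
    catalog = "InversionCatalog"
  )
)

setValidity("KaryotypeMatrix", function(object) {
  st <- object@states
  if (is.null(rownames(st)) || is.null(colnames(st)))
    return("states matrix must have taxon rownames and inversion colnames")
  if (anyDuplicated(rownames(st))) return("taxon labels must be unique")
  cat <- object@catalog
  if (!setequal(colnames(st), cat@inversions$name))
    return("state columns must cover exactly the catalog inversions")
  ok <- st %in% c("standard", "inverted") | is.na(st)
  if (!all(ok)) return("states must be 'standard', 'inverted' or NA")
  if (length(object@outgroup) > 1L)
    return("at most one outgroup")
  if (length(object@outgroup) == 1L && !object@outgroup %in% rownames(st))
    return("outgroup must be one of the taxa")
  TRUE
})

#' Mate-pair library specification
#'
#' @slot insertSize nominal insert size in bp.
#' @slot insertSd standard deviation of the insert size in bp.
#' @slot readLength read length in bp.
#' @slot orientation pair-orientation convention for concordant pairs
#'   (`"FR"`: forward read upstream of reverse-complemented mate).
#' @exportClass LibrarySpec
setClass("LibrarySpec",
  representation(
    insertSize = "numeric",
    insertSd = "numeric",
    readLength = "integer",
    orientation = "character"
  )
)

setValidity("LibrarySpec", function(object) {
  if (object@insertSize <= 2 * object@readLength)
    return("insert size must exceed twice the read length")
  if (object@insertSd < 0) return("insert sd must be >= 0")
  if (!object@orientation %in% "FR") return("only the FR orientation convention is supported")
  TRUE
})

#' Model of a miniature inverted-repeat transposable element (MITE)
#'
#' @slot name element name.
#' @slot consensus consensus sequence between the inferred 5' and 3'
#'   boundaries.
#' @slot tsdLength inferred target-site-duplication length in bp.
#' @slot copies genomic coordinates of the element copies
#'   ([GenomicRanges::GRanges]) with per-copy boundaries.
#' @exportClass MITEModel
setClass("MITEModel",
  representation(
    name = "character",
    consensus = "DNAString",
    tsdLength = "integer",
    copies = "GRanges"
  )
)

#' Result of one outgroup-ancestry scenario
#'
#' Minimum-event reconstruction for one hypothesised ancestral X arrangement:
#' all minimum-event topologies, the event total, and per-inversion origin
#' counts for each optimal topology.
#'
#' @slot scenario scenario label (the ancestral X-arrangement state).
#' @slot totalEvents minimum total number of inversion fixation events.
#' @slot trees list of optimal topologies ([ape::phylo]), ordered by their
#'   canonical Newick string.
#' @slot newick canonical Newick strings of the optimal topologies.
#' @slot origins list (parallel to `trees`) of named integer vectors: number
#'   of independent state flips of each inversion in the backtracked optimal
#'   labeling.
#' @slot details list (parallel to `trees`) with the per-edge event
#'   placements and internal node states.
#' @exportClass ScenarioResult
setClass("ScenarioResult",
  representation(
    scenario = "character",
    totalEvents = "integer",
    trees = "list",
    newick = "character",
    origins = "list",
    details = "list"
  )
)

## ---- show methods -------------------------------------------------------

setMethod("show", "InversionCatalog", function(object) {
  inv <- object@inversions
  cat("InversionCatalog:", object@description, "\n")
  cat(sprintf("  %d inversions on %d arm(s): %s\n",
              nrow(inv), length(unique(inv$arm)),
              paste(unique(inv$arm), collapse = ", ")))
  for (arm in unique(inv$arm)) {
    nm <- inv$name[inv$arm == arm]
    cat(sprintf("  %-3s: %s\n", arm, paste(nm, collapse = ", ")))
  }
})

setMethod("show", "SegmentMap", function(object) {
  cat(sprintf("SegmentMap for arm %s: %d segments, %d breakpoints\n",
              object@arm, object@n, length(object@breakpoints)))
})

setMethod("show", "SignedPermutation", function(object) {
  cat(sprintf("SignedPermutation [%s]: (%s)\n", object@arm,
              paste(object@elements, collapse = ",")))
})

setMethod("show", "KaryotypeMatrix", function(object) {
  cat(sprintf("KaryotypeMatrix: %d taxa x %d inversions\n",
              nrow(object@states), ncol(object@states)))
  if (length(object@outgroup)) cat("  outgroup:", object@outgroup, "\n")
  inv <- apply(object@states, 1L, function(r)
    paste(colnames(object@states)[!is.na(r) & r == "inverted"], collapse = " "))
  for (i in seq_along(inv))
    cat(sprintf("  %-18s %s\n", rownames(object@states)[i],
                if (nzchar(inv[i])) inv[i] else "(all standard)"))
})

setMethod("show", "LibrarySpec", function(object) {
  cat(sprintf("LibrarySpec: insert %g +/- %g bp, reads %d bp, %s\n",
              object@insertSize, object@insertSd, object@readLength,
              object@orientation))
})

setMethod("show", "MITEModel", function(object) {
  cat(sprintf("MITEModel %s: %d bp consensus, %d copies, TSD %d bp\n",
              object@name, length(object@consensus), length(object@copies),
              object@tsdLength))
})

setMethod("show", "ScenarioResult", function(object) {
  cat(sprintf("Scenario %s: %d events, %d optimal topolog%s\n",
              object@scenario, object@totalEvents, length(object@trees),
              if (length(object@trees) == 1L) "y" else "ies"))
  if (length(object@origins)) {
    o <- object@origins[[1L]]
    multi <- names(o)[o > 1L]
    if (length(multi))
      cat("  inversions with multiple origins:",
          paste(sprintf("%s (%d)", multi, o[multi]), collapse = ", "), "\n")
    else cat("  all inversions originate once\n")
  }
})
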