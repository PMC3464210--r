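#' Karyotype matrix of the An. gambiae complex with an outgroup
#'
#' The seven ingroup species' fixed-inversion arrangement states plus an
#' outgroup taxon.  Autosomal outgroup states follow the established
#' ancestries: 2Ro inverted, 2Rp standard, 2La inverted (3La and 2Rm
#' standard); the ancestral X arrangement is the hypothesis under test and is
#' set by `outgroupX`.  2La is coded fixed-inverted in An. gambiae (its
#' polymorphic 2La/+ status is recorded as an attribute, not as a state).
#'
#' @param outgroupX hypothesised ancestral X arrangement: `"Xag"`, `"X+"` or
#'   `"Xbcd"`.
#' @param outgroupLabel taxon label for the outgroup.
#' @return A [KaryotypeMatrix-class].
#' @export
gambiaeKaryotypeMatrix <- function(outgroupX = c("Xag", "X+", "Xbcd"),
                                   outgroupLabel = "outgroup") {
  outgroupX <- match.arg(outgroupX)
  catalog <- gambiaeComplexCatalog()
  invs <- catalog@inversions$name
  taxa <- c("gambiae", "merus", "arabiensis", "quadriannulatusA",
            "quadriannulatusB", "bwambae", "melas", outgroupLabel)
  st <- matrix("standard", length(taxa), length(invs),
               dimnames = list(taxa, invs))
  invert <- function(tx, nm) st[tx, nm] <<- "inverted"
  invert("gambiae", c("Xa", "Xg", "2La"))
  invert("merus", c("Xa", "Xg", "2Ro", "2Rp", "2La"))
  invert("arabiensis", c("Xb", "Xc", "Xd", "2La"))
  invert("bwambae", "3La")
  invert("melas", c("3La", "2Rm"))
  invert(outgroupLabel, c("2Ro", "2La"))
  invert(outgroupLabel, .xOptionInversions(outgroupX, catalog))
  out <- new("KaryotypeMatrix", states = st, outgroup = outgroupLabel,
             catalog = catalog)
  attr(out, "polymorphic") <- data.frame(taxon = "gambiae", inversion = "2La",
                                         note = "2La/+ polymorphic; coded fixed-inverted")
  out
}

#' Construct a karyotype matrix
#'
#' @param states character matrix of `"standard"`/`"inverted"` (rows = taxa,
#'   columns = inversion names covering the catalog).
#' @param catalog an [InversionCatalog-class].
#' @param outgroup outgroup taxon label, or `character(0)`.
#' @return A [KaryotypeMatrix-class].
#' @export
karyotypeMatrix <- function(states, catalog, outgroup = character(0)) {
  new("KaryotypeMatrix", states = states, outgroup = outgroup,
      catalog = catalog)
}

## X-arm inversions implied by an ancestral-X scenario label, e.g.
## "Xag" -> Xa, Xg; "X+" -> none.
.xOptionInversions <- function(option, catalog) {
  if (option == "X+") return(character(0))
  letters1 <- strsplit(sub("^X", "", option), "")[[1L]]
  nm <- paste0("X", letters1)
  bad <- setdiff(nm, catalog@inversions$name)
  if (length(bad)) stop("unknown X inversion(s) in scenario: ", paste(bad, collapse = ","))
  nm
}

## ---- arm state graphs -----------------------------------------------------
##
## The node set of an arm's state graph is every permutation reachable from
## the identity by valid inversion flips; edges are single flips labelled by
## inversion.  Because flip validity depends on the realised junctions (not
## only on the binary states), nodes are permutations; each carries the
## binary arrangement-state labelling implied by its flip history.

.armStateGraph <- function(catalog, arm, maxStates = 4096L) {
  map <- buildSegmentMap(catalog, arm)
  invNames <- catalog@inversions$name[catalog@inversions$arm == arm]
  id <- seq_len(map@n)
  keyOf <- function(p) paste(p, collapse = ",")
  perms <- list(id)
  keys <- keyOf(id)
  states <- matrix(FALSE, 1L, length(invNames), dimnames = list(NULL, invNames))
  eFrom <- integer(); eTo <- integer(); eInv <- character()
  qi <- 1L
  while (qi <= length(perms)) {
    p <- perms[[qi]]
    st <- setNames(as.logical(states[qi, ]), invNames)
    for (nm in invNames) {
      q <- .flipInversion(p, catalog, map, nm,
                          if (st[[nm]]) "inverted" else "standard")
      if (is.null(q)) next
      k <- keyOf(q)
      j <- match(k, keys)
      newst <- st
      newst[[nm]] <- !newst[[nm]]
      if (is.na(j)) {
        perms[[length(perms) + 1L]] <- q
        keys <- c(keys, k)
        states <- rbind(states, newst)
        j <- length(perms)
        if (j > maxStates) stop("arm state space exceeds limit on arm ", arm)
      } else if (!identical(unname(states[j, ]), unname(newst))) {
        stop("ambiguous arrangement-state labelling on arm ", arm)
      }
      eFrom <- c(eFrom, qi); eTo <- c(eTo, j); eInv <- c(eInv, nm)
    }
    qi <- qi + 1L
  }
  S <- length(perms)
  adj <- lapply(seq_len(S), function(i) {
    sel <- eFrom == i
    list(to = eTo[sel], inv = eInv[sel])
  })
  # all-pairs shortest flip paths with predecessors (deterministic BFS,
  # neighbours in catalog order)
  D <- matrix(Inf, S, S)
  pred <- matrix(NA_integer_, S, S)      # pred[src, v]: previous node on path src->v
  predInv <- matrix(NA_character_, S, S)
  for (src in seq_len(S)) {
    D[src, src] <- 0
    queue <- src
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- adj[[v]]
      for (ii in seq_along(nb$to)) {
        w <- nb$to[ii]
        if (is.infinite(D[src, w])) {
          D[src, w] <- D[src, v] + 1
          pred[src, w] <- v
          predInv[src, w] <- nb$inv[ii]
          queue <- c(queue, w)
        }
      }
    }
  }
  list(arm = arm, map = map, invNames = invNames, perms = perms, keys = keys,
       states = states, adj = adj, D = D, pred = pred, predInv = predInv)
}

## Flip labels along the shortest path src -> dst (deterministic).
.graphPath <- function(graph, src, dst) {
  if (src == dst) return(character(0))
  if (is.infinite(graph$D[src, dst])) stop("unreachable arm states")
  path <- character(0)
  v <- dst
  while (v != src) {
    path <- c(graph$predInv[src, v], path)
    v <- graph$pred[src, v]
  }
  path
}

## Node index of the canonical encoding of one taxon's states on an arm.
.canonicalNode <- function(graph, catalog, states) {
  p <- permElements(encodeKaryotype(states, catalog, arms = graph$arm)[[1L]])
  j <- match(paste(p, collapse = ","), graph$keys)
  if (is.na(j)) stop("canonical arrangement not in arm state graph")
  j
}

.armGraphs <- function(catalog) {
  graphs <- lapply(catalogArms(catalog), function(a) .armStateGraph(catalog, a))
  names(graphs) <- catalogArms(catalog)
  graphs
}

## Leaf cost matrices (S x ntaxa, 0 at the canonical node, Inf elsewhere).
.leafCosts <- function(graphs, kmat) {
  taxa <- rownames(kmat@states)
  lapply(graphs, function(g) {
    m <- matrix(Inf, length(g$perms), length(taxa),
                dimnames = list(NULL, taxa))
    for (tx in taxa) {
      node <- .canonicalNode(g, kmat@catalog, kmat@states[tx, ])
      m[node, tx] <- 0
    }
    m
  })
}

#' Enumerate unrooted binary topologies
#'
#' All `(2n-5)!!` unrooted binary trees on the given taxa, in the
#' deterministic order produced by [phangorn::allTrees].
#'
#' @param taxa taxon labels (3 to 8).
#' @return List of [ape::phylo] trees.
#' @export
enumerateTopologies <- function(taxa) {
  n <- length(taxa)
  if (n < 3L || n > 8L) stop("topology enumeration supports 3 to 8 taxa")
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
  lapply(seq_along(trees), function(i) trees[[i]])
}

#' Canonical Newick string of a topology
#'
#' The unrooted topology is re-rooted on its lexicographically smallest tip
#' and clades are ordered by smallest descendant label, so topologically
#' identical trees print identically regardless of representation.
#'
#' @param tree an [ape::phylo]; branch lengths and rooting are ignored.
#' @return Newick string (no branch lengths).
#' @export
canonicalNewick <- function(tree) {
  if (length(tree$tip.label) > 3L && ape::is.rooted(tree)) tree <- ape::unroot(tree)
  tree <- ape::root(tree, outgroup = sort(tree$tip.label)[1L],
                    resolve.root = TRUE)
  n <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  build <- function(node) {
    if (node <= n) return(list(str = tree$tip.label[node], min = tree$tip.label[node]))
    parts <- lapply(kids[[as.character(node)]], build)
    mins <- vapply(parts, `[[`, "", "min")
    o <- order(mins)
    list(str = paste0("(", paste(vapply(parts[o], `[[`, "", "str"), collapse = ","), ")"),
         min = mins[o[1L]])
  }
  root <- n + 1L
  paste0(build(root)$str, ";")
}

#' Score one topology by trajectory-constrained inversion parsimony
#'
#' Minimum total number of inversion fixation events needed to explain the
#' taxa's arrangement states on the given topology.  Each chromosome arm is
#' scored by Sankoff small parsimony over the arm's state graph: internal
#' nodes range over all arrangements reachable from the reference by valid
#' flips, edge costs are shortest valid-flip path lengths, and leaves are
#' anchored at the canonical (junction-attested) encoding of their states.
#' Per-inversion origin counts and per-edge event placements come from a
#' deterministic backtrack of one optimal labelling.
#'
#' @param tree an [ape::phylo] (rooted or unrooted) whose tips are the
#'   matrix taxa.
#' @param kmat a [KaryotypeMatrix-class].
#' @param graphs optional precomputed arm state graphs (internal use).
#' @return list with `totalEvents`, `origins` (named integer vector of state
#'   flips per inversion), `edgeEvents` (data.frame: edge, parent, child,
#'   inversion), `nodeStates` (taxa + internal arrangements as a logical
#'   matrix of inverted states), and `perArm` event totals.
#' @export
scoreTree <- function(tree, kmat, graphs = NULL) {
  catalog <- kmat@catalog
  taxa <- rownames(kmat@states)
  if (!setequal(tree$tip.label, taxa)) stop("tree tips must match matrix taxa")
  if (is.null(graphs)) graphs <- .armGraphs(catalog)
  tr <- stats::reorder(tree, "postorder")
  nt <- length(tr$tip.label)
  nnode <- nt + tr$Nnode
  e <- tr$edge
  root <- nt + 1L

  totals <- numeric(length(graphs)); names(totals) <- names(graphs)
  origins <- setNames(integer(nrow(catalog@inversions)), catalog@inversions$name)
  edgeEvents <- NULL
  nodeStates <- matrix(FALSE, nnode, nrow(catalog@inversions),
                       dimnames = list(NULL, catalog@inversions$name))

  for (armName in names(graphs)) {
    g <- graphs[[armName]]
    S <- length(g$perms)
    C <- matrix(0, nnode, S)
    for (tx in tr$tip.label) {
      node <- .canonicalNode(g, catalog, kmat@states[tx, ])
      i <- match(tx, tr$tip.label)
      C[i, ] <- Inf
      C[i, node] <- 0
    }
    choice <- vector("list", nrow(e))
    for (i in seq_len(nrow(e))) {
      par <- e[i, 1L]; ch <- e[i, 2L]
      pick <- integer(S); add <- numeric(S)
      for (s in seq_len(S)) {
        v <- C[ch, ] + g$D[, s]
        pick[s] <- which.min(v)    # first minimum: deterministic tie-break
        add[s] <- v[pick[s]]
      }
      choice[[i]] <- pick
      C[par, ] <- C[par, ] + add
    }
    totals[armName] <- min(C[root, ])
    # backtrack one optimal labelling
    assign <- integer(nnode)
    assign[root] <- which.min(C[root, ])
    for (i in rev(seq_len(nrow(e)))) {
      par <- e[i, 1L]; ch <- e[i, 2L]
      assign[ch] <- choice[[i]][assign[par]]
    }
    for (nd in seq_len(nnode))
      nodeStates[nd, g$invNames] <- as.logical(g$states[assign[nd], ])
    for (i in seq_len(nrow(e))) {
      flips <- .graphPath(g, assign[e[i, 1L]], assign[e[i, 2L]])
      for (nm in flips) origins[nm] <- origins[nm] + 1L
      if (length(flips))
        edgeEvents <- rbind(edgeEvents,
                            data.frame(edge = i, parent = e[i, 1L],
                                       child = e[i, 2L], inversion = flips,
                                       stringsAsFactors = FALSE))
    }
  }
  rownames(nodeStates) <- c(tr$tip.label, paste0("node", (nt + 1L):nnode))
  list(totalEvents = as.integer(sum(totals)), origins = origins,
       edgeEvents = edgeEvents, nodeStates = nodeStates,
       perArm = totals, tree = tr)
}

## Batch scores for many topologies via the compiled Sankoff scan.
.scanTopologies <- function(trees, kmat, graphs, leafCosts = NULL) {
  taxa <- rownames(kmat@states)
  if (is.null(leafCosts)) leafCosts <- .leafCosts(graphs, kmat)
  edges <- lapply(trees, function(tr) {
    tr2 <- stats::reorder(tr, "postorder")
    # tips in trees must be numbered in `taxa` order
    idx <- match(tr2$tip.label, taxa)
    if (anyNA(idx)) stop("tree tips must match matrix taxa")
    e <- tr2$edge
    e[e[, 2L] <= length(taxa), 2L] <- idx[e[e[, 2L] <= length(taxa), 2L]]
    e
  })
  Ds <- lapply(graphs, `[[`, "D")
  sankoff_scan(edges, length(taxa), unname(leafCosts), unname(Ds))
}

#' Minimum-event trees under alternative outgroup X ancestries
#'
#' For each hypothesised ancestral X-chromosome arrangement, sets the
#' outgroup taxon's X states accordingly, scores every unrooted binary
#' topology by [scoreTree]'s criterion, and reports all minimum-event
#' topologies with per-inversion origin counts.  The winner is the scenario
#' whose optimum explains every inversion by a single origin; ties are
#' reported, not broken.
#'
#' @param kmat a [KaryotypeMatrix-class] with a designated outgroup.
#' @param xOptions ancestral X arrangement labels (e.g.
#'   `c("X+", "Xbcd", "Xag")`).
#' @return list with `scenarios` (list of [ScenarioResult-class]), `winner`
#'   (label of the unique single-origin scenario, or `NA`), and
#'   `singleOrigin` (logical per scenario).
#' @export
bestScenario <- function(kmat, xOptions = c("X+", "Xbcd", "Xag")) {
  if (!length(xOptions)) stop("xOptions must be non-empty")
  if (!length(kmat@outgroup)) stop("karyotype matrix has no outgroup")
  catalog <- kmat@catalog
  graphs <- .armGraphs(catalog)
  taxa <- rownames(kmat@states)
  trees <- if (length(taxa) == 2L) NULL else enumerateTopologies(taxa)
  xInv <- catalog@inversions$name[catalog@inversions$arm == "X"]

  scenarios <- lapply(xOptions, function(opt) {
    km <- kmat
    km@states[km@outgroup, xInv] <- "standard"
    km@states[km@outgroup, .xOptionInversions(opt, catalog)] <- "inverted"
    if (is.null(trees)) {
      # two taxa: single topology, events = pairwise distance
      perms <- lapply(taxa, function(tx) encodeKaryotype(km@states[tx, ], catalog))
      d <- sum(mapply(function(p, q) reversalDistance(p, q),
                      perms[[1L]], perms[[2L]]))
      tr <- ape::read.tree(text = paste0("(", taxa[1L], ",", taxa[2L], ");"))
      return(new("ScenarioResult", scenario = opt, totalEvents = as.integer(d),
                 trees = list(tr), newick = canonicalNewick(tr),
                 origins = list(setNames(integer(0), character(0))),
                 details = list(NULL)))
    }
    sc <- .scanTopologies(trees, km, graphs)
    best <- min(sc)
    opt_idx <- which(sc == best)
    det <- lapply(opt_idx, function(i) scoreTree(trees[[i]], km, graphs))
    nwk <- vapply(opt_idx, function(i) canonicalNewick(trees[[i]]), "")
    o <- order(nwk)
    new("ScenarioResult", scenario = opt,
        totalEvents = as.integer(best),
        trees = lapply(opt_idx[o], function(i) trees[[i]]),
        newick = nwk[o],
        origins = lapply(det[o], `[[`, "origins"),
        details = det[o])
  })
  names(scenarios) <- xOptions
  singleOrigin <- vapply(scenarios, function(s)
    any(vapply(s@origins, function(o) all(o[o > 0L] == 1L) && length(o), TRUE)),
    TRUE)
  winner <- if (sum(singleOrigin) == 1L) xOptions[singleOrigin] else NA_character_
  list(scenarios = scenarios, winner = winner, singleOrigin = singleOrigin)
}

#' Root a topology on its outgroup
#'
#' @param tree an [ape::phylo].
#' @param outgroup outgroup tip label.
#' @return Rooted [ape::phylo] with the root on the outgroup edge.
#' @export
rootTree <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label) stop("outgroup absent from tree")
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Replay edge events from the root and recover leaf karyotypes
#'
#' Applies the backtracked per-edge inversion flips of a [scoreTree] result
#' along every root-to-leaf path, starting from the root arrangement, and
#' returns the resulting leaf states.  Agreement with the observed karyotype
#' matrix verifies that each event is placed on exactly one edge and that
#' the placements are trajectory-valid.
#'
#' @param score result of [scoreTree].
#' @param kmat the scored [KaryotypeMatrix-class].
#' @return Logical matrix of replayed inverted-states (taxa x inversions).
#' @export
replayEvents <- function(score, kmat) {
  tr <- score$tree
  nt <- length(tr$tip.label)
  root <- nt + 1L
  inv <- colnames(score$nodeStates)
  st <- matrix(NA, nt, length(inv), dimnames = list(tr$tip.label, inv))
  walk <- function(node, cur) {
    if (node <= nt) { st[node, ] <<- cur; return(invisible()) }
    for (i in which(tr$edge[, 1L] == node)) {
      nxt <- cur
      ev <- score$edgeEvents
      if (!is.null(ev)) {
        flips <- ev$inversion[ev$edge == i]
        for (nm in flips) nxt[[nm]] <- !nxt[[nm]]
      }
      walk(tr$edge[i, 2L], nxt)
    }
  }
  walk(root, score$nodeStates[root, ])
  st
}
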