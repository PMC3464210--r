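## Shared fixtures and independent oracles for the test suite.

suppressPackageStartupMessages({
  library(Biostrings)
  library(GenomicRanges)
  library(ape)
})

## 2R states shorthand
st2R <- function(o, p) c(`2Ro` = o, `2Rp` = p)

## Toy catalog: non-overlapping single-segment inversions per arm.
toyCatalog <- function(armInvs = c(A = 2L, B = 1L)) {
  rows <- NULL
  for (arm in names(armInvs)) {
    for (i in seq_len(armInvs[[arm]])) {
      nm <- paste0(arm, i)
      rows <- rbind(rows, data.frame(
        name = nm, arm = arm, bpDistal = 2 * i - 1, bpProximal = 2 * i,
        anchorDistalTel = paste0(nm, ".dT"), anchorDistalCen = paste0(nm, ".dC"),
        anchorProximalTel = paste0(nm, ".pT"), anchorProximalCen = paste0(nm, ".pC"),
        stringsAsFactors = FALSE))
    }
  }
  inversionCatalog(rows, description = "toy")
}

## All signed permutations of 1..n (list of integer vectors).
allSignedPerms <- function(n) {
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (s in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], s)
    out
  }
  out <- list()
  for (p in perms(seq_len(n))) {
    for (bits in 0:(2^n - 1)) {
      sgn <- ifelse(bitwAnd(bits, 2^(seq_len(n) - 1L)) > 0L, -1L, 1L)
      out[[length(out) + 1L]] <- as.integer(p * sgn)
    }
  }
  out
}

## Independent small-parsimony oracle: brute force over internal labelings
## of independent binary characters (valid only for non-overlapping
## inversions, where every flip is unconstrained).
bruteForceParsimony <- function(tree, kmat) {
  tr <- stats::reorder(tree, "postorder")
  nt <- length(tr$tip.label)
  nnode <- nt + tr$Nnode
  internals <- (nt + 1L):nnode
  inv <- colnames(kmat@states)
  total <- 0L
  for (nm in inv) {
    leaf <- kmat@states[tr$tip.label, nm] == "inverted"
    best <- Inf
    for (mask in 0:(2^length(internals) - 1L)) {
      assign <- logical(nnode)
      assign[seq_len(nt)] <- leaf
      assign[internals] <- bitwAnd(mask, 2^(seq_along(internals) - 1L)) > 0L
      ch <- sum(assign[tr$edge[, 1L]] != assign[tr$edge[, 2L]])
      if (ch < best) best <- ch
    }
    total <- total + best
  }
  total
}

## Random single-origin inversion history on a random rooted tree.
simulateHistory <- function(nIngroup = 7L, nInv = 10L, seed = 1L) {
  set.seed(seed)
  nArms <- 3L
  counts <- tabulate(sample(nArms, nInv, replace = TRUE), nbins = nArms)
  counts[counts == 0L] <- 1L
  armInvs <- setNames(as.integer(counts), c("A", "B", "C"))
  catalog <- toyCatalog(armInvs)
  invs <- catalog@inversions$name
  taxa <- c(paste0("t", seq_len(nIngroup)), "outgroup")
  tr <- ape::rtree(length(taxa), tip.label = sample(taxa))
  tr <- ape::root(tr, "outgroup", resolve.root = TRUE)
  nt <- length(taxa)
  edgeOf <- sample(nrow(tr$edge), length(invs), replace = TRUE)
  # leaf states: inversion flipped below its edge
  below <- function(node) {
    if (node <= nt) return(node)
    unlist(lapply(tr$edge[tr$edge[, 1L] == node, 2L], below))
  }
  st <- matrix("standard", nt, length(invs), dimnames = list(taxa, invs))
  for (k in seq_along(invs)) {
    tips <- tr$tip.label[below(tr$edge[edgeOf[k], 2L])]
    st[tips, invs[k]] <- "inverted"
  }
  list(kmat = karyotypeMatrix(st, catalog, outgroup = "outgroup"),
       tree = tr, catalog = catalog)
}
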