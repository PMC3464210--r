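---
title: "Rooting a chromosomal phylogeny from fixed inversions"
author: "chromoPhylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rooting a chromosomal phylogeny from fixed inversions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromoPhylo)
```

## The problem

Sibling-species complexes such as the *Anopheles gambiae* complex are too
recently diverged, and too permeated by introgression, for nucleotide markers
to root their phylogeny reliably. Fixed paracentric inversions behave better:
they are rare, effectively non-introgressing, and — because overlapping
inversions constrain which orders of events are physically possible — they
carry directional information. The complex's ten fixed inversions (Xa, Xg,
Xb, Xc, Xd on the X; 2Ro, 2Rp, 2Rm on 2R; 2La on 2L; 3La on 3L) are the
characters; outgroup genomes (*An. stephensi*, *Culex quinquefasciatus*,
*Aedes aegypti*) supply the ancestral states at the breakpoints.

`chromoPhylo` implements that inference chain as testable code: karyotypes
are encoded as signed permutations of chromosome-arm segments, inversion
events are reversals constrained to cut at their breakpoint junctions, trees
are scored by minimum event count under those constraints, breakpoints are
detected from same-orientation discordant mate pairs, arrangement states are
called from breakpoint-flanking gene adjacencies, and novel repeat elements
at breakpoints are delimited together with their target-site duplication
(TSD). A seeded generator produces synthetic genomes, mate-pair libraries,
karyotype histories and element insertions with machine-readable truth, so
every step is exercised against known answers.

## Karyotypes as signed permutations

Each arm is partitioned into segments by the catalogued breakpoints; `n`
distinct breakpoints give `n + 1` segments, and the all-standard reference
arrangement is the identity permutation. A paracentric inversion reverses a
block's order and orientation (signs). The catalogued 2R map built from the
two molecularly mapped inversions has five segments, delimited by the 2Ro
breakpoints (between AGAP001760|AGAP001762 and AGAP002933|AGAP002935) and
the 2Rp breakpoints (AGAP001983|AGAP001984 and AGAP003327|AGAP003328):

```{r}
cat2 <- catalog2Rop()
merus2R <- encodeKaryotype(c(`2Ro` = "inverted", `2Rp` = "inverted"), cat2)[["2R"]]
merus2R
junctionAdjacencies(merus2R, buildSegmentMap(cat2, "2R"))
```

The junctions recover the gene pairs observed at the *An. merus* 2Ro
breakpoints (AGAP001760 with AGAP002933; AGAP001762 with AGAP002935).

**Trajectory constraint.** A state flip of inversion *v* is valid in
arrangement $\pi$ iff a single reversal exists whose two cut adjacencies are
exactly *v*'s breakpoint junctions: flipping to the inverted state must cut
both junctions (they must be intact in $\pi$), flipping back must restore
both. For the overlapping 2Ro/2Rp pair this forbids exactly the event order
the cytogenetics forbids — from the double-inverted 2Rop arrangement, 2Rp
can be undone first but 2Ro cannot:

```{r}
validateTrajectory(list(
  c(`2Ro` = "inverted", `2Rp` = "inverted"),
  c(`2Ro` = "inverted", `2Rp` = "standard"),
  c(`2Ro` = "standard", `2Rp` = "standard")), cat2)$valid
validateTrajectory(list(
  c(`2Ro` = "inverted", `2Rp` = "inverted"),
  c(`2Ro` = "standard", `2Rp` = "inverted"),
  c(`2Ro` = "standard", `2Rp` = "standard")), cat2)$valid
```

Two modelling choices deserve mention. First, "2Ro and 2Rp both inverted"
has two geometric realisations, depending on which inversion happened first;
`encodeKaryotype` composes flips in catalog order, which yields the
realisation whose junctions are actually attested in *An. merus*, and
`validateTrajectory` anchors the final state of a trajectory to this
canonical encoding — that makes the validity check direction-independent.
Second, since no machine-readable breakpoint coordinates exist for the five
X inversions, they are modelled as mutually non-overlapping single-segment
intervals with distinct breakpoints (11 segments). Sharing breakpoints
between adjacent inversions would make the composed Xag and Xbcd karyotypes
unencodable under the contiguity rule, so distinct breakpoints are the only
layout consistent with the character logic; it preserves the event counts
(Xag = 2, Xbcd = 3) that the scenario analysis relies on. 2Rm, whose
breakpoint genes are uncharacterised, is placed proximal to 2Rp and
non-overlapping; the full-complex 2R map therefore has seven segments.

## Reversal distances

`reversalDistance` implements the exact signed reversal distance via the
breakpoint graph, $d = (n + 1) - c + h + f$ with $c$ cycles, $h$ hurdles and
fortress indicator $f$. Because hurdle bookkeeping is notoriously easy to
get subtly wrong, the package carries its own arbiter:
`reversalDistanceBFS`, an exhaustive breadth-first search over the reversal
graph (guarded to $n \le 8$, implemented in C++). The test suite checks
agreement on **every** signed permutation with $n \le 5$ (4,282 cases) and
on 1,000 random pairs at $n \le 7$. `minimalSortingSequences` enumerates all
minimum-length reversal scenarios (deterministic lexicographic order,
guarded to distance 4); on the merus-to-gambiae 2R pair it returns exactly
the undo-2Rp-then-undo-2Ro orders and never an undo-2Ro-first order.

## Scenario analysis and rooting

`scoreTree` scores a topology by Sankoff small parsimony, per arm, over the
**arm state graph**: every arrangement reachable from the reference by valid
flips (10 arrangements on 2R, 32 on the X), with edge costs equal to
shortest valid-flip path lengths. Leaves are anchored at the canonical
encoding of their observed states; internal nodes may take any reachable
arrangement. This is the trajectory-validated restriction of internal states
to arrangement combinations; for matrices of non-overlapping inversions it
reduces to independent binary-character parsimony, which the tests verify
against a brute-force enumeration oracle. Per-inversion origin counts (the
number of edges on which a state flips) come from a deterministic backtrack.

`bestScenario` repeats an exhaustive scan of all unrooted binary topologies
(10,395 at eight taxa; the scan itself is compiled) for each hypothesised
ancestral X arrangement, holding the autosomal outgroup states at the
breakpoint-established ancestries (2Ro inverted, 2Rp standard, 2La
inverted):

```{r, eval = FALSE}
km <- gambiaeKaryotypeMatrix()
bs <- bestScenario(km, c("X+", "Xbcd", "Xag"))
bs$winner
#> [1] "Xag"
```

Under the Xag ancestry the optimum needs 10 events — one origin per
inversion; under X+ or Xbcd it needs 11, and an optimal labelling always
exists that places the extra event as a second origin of 2Ro. All
minimum-event topologies are reported (ordered by a canonical Newick form);
the quadriannulatus A/B pair, at rearrangement distance zero, makes the
optimum a set of resolutions rather than a single tree, and ties are never
broken silently. `rootTree` roots the winner on the outgroup edge and
`replayEvents` re-applies the backtracked per-edge events from the root,
verifying that each event sits on exactly one edge and regenerates every
leaf karyotype.

## Mate-pair breakpoint detection

The detector mirrors the logic of long-insert mate-pair sequencing: pairs of
36-bp reads from 2/3/5-kb circularised fragments, mapped to a reference in
which the sample carries an inversion, map far apart **in the same
orientation** when their fragment spans an inversion junction. Mapping is
unique exact matching (seed of 20 bp verified over the full read, both
strands; multimappers are dropped, which is also why repeat-laden
breakpoints like 2Rp's defeat the approach). Classification uses a declared
FR convention with a concordance window of `insertSize ± 3·insertSd`;
same-strand pairs are the inversion signal. The `++` and `--` pairs of one
inversion are clustered together and each cluster yields two reciprocal
calls from the pairs' hard geometric constraints (`b1 ≥ max(p) + rl`,
`b1 ≤ min(u)`; `b2 ≥ max(r) + rl`, `b2 ≤ min(v)`), which do not depend on
the insert-size distribution — deliberately so, because Normal insert tails
at realistic pair counts break any bound of the form `insert + k·sd`. A
12-bp guard band absorbs reads that overhang a junction by `k` bases yet
still map because the flanking bases coincide by chance (probability
`4^-k`). Each interval is capped at one maximal insert; at 30x coverage on
a 4-Mb toy genome with breakpoints planted at 1:10-scale coordinates
(948 kb / 2,984 kb) the reported intervals are a few tens of base pairs
wide and contain the true coordinates.

**Detection limit.** A junction whose breakpoint region is `g` bp of novel
sequence is spannable iff some library satisfies
`insertSize >= g + 2·readLength`. `detectionLimit` verifies this by
simulation; with the 2/3/5-kb design the largest detectable gap at 1-kb
resolution is 4 kb, i.e. regions longer than 5 kb are never detected. For
this analysis the libraries default to fixed-size inserts (sd 0): the limit
is a property of the nominal insert, and Gaussian insert tails would blur
the geometric boundary the analysis is meant to expose. The general
simulator keeps Normal(insert, 0.1·insert) inserts as its default.

## Arrangement calls from gene adjacencies

`inferArrangementState` compares a species' observed breakpoint-flanking
gene adjacencies (ortholog-mapped, alias-resolved) against **diagnostic
junction models**: anchor pairs that occur in some arrangement carrying the
inversion but in none without it, and vice versa. For an isolated inversion
these are the familiar two-junction models; for overlapping inversions the
attested junctions depend on the background (the 2Rp junctions realised on
the 2Ro background differ from those on the standard background), so the
models are derived from the full arm state graph. Anchors found on different
scaffolds leave a species unresolved, and unresolved species never
contribute to the ancestry vote; adjacencies matching both models raise a
conflict flag.

## MITE boundaries and TSD

`findRepeatCopies` reports maximal exact matches (seeded, both strands)
between a candidate breakpoint-region sequence and the genome — an exact
local matcher is the appropriate instrument for the error-free synthetic
genomes this package analyses. `defineElementBoundaries` then extracts every
copy with 1000-bp flanks and stacks the windows into a column profile
anchored on the shared repeat core. A progressive pairwise merge with cheap
gap penalties was evaluated for this step and rejected: on windows that are
mostly unrelated flank it places spurious gaps that corrupt the profile,
while the copies, having no indels, are already exactly aligned by their
core diagonal. The element is the maximal run of columns whose mean pairwise
identity over a sliding 10-bp window stays at or above 0.5 (flanks sit near
0.25); per-copy termini are then fixed by locating the defined consensus in
each window. The TSD is the longest direct repeat (up to 20 bp) immediately
flanking both termini, aggregated across copies by majority vote with ties
resolved toward the shorter length — chance flank matches occasionally
lengthen a single copy's repeat, and the vote removes them. On planted
elements with 3-bp TSDs the procedure recovers `tsdLength = 3` and termini
within ±1 bp across 20 seeded replicates.

## The synthetic-data generator

All inputs the analysis assumes can be generated with recorded truth:
random genomes with non-overlapping genes (`simulateAncestralGenome`),
catalog realisations with per-segment marker 36-mers and breakpoint-flanking
anchors (`realizeCatalog`), karyotype histories on trees with per-edge
events validated for trajectory contiguity (`evolveKaryotypes`), single
inversions with optional novel junction sequence
(`simulateInversionGenome`), mate-pair libraries
(`simulateMatePairLibrary`; pair count `ceiling(cov·L / (2·readLength))`,
truncated-Normal inserts, FR orientation, error-free by default with an
optional substitution rate), and MITE insertions with target-site
duplication (`plantMite`). Everything is deterministic under a mandatory
seed (R's default generator; the caller's RNG state is restored).

What the generator deliberately does **not** emulate: sequencing errors and
quality models, indels, repetitive background beyond the planted elements,
assembly fragmentation, and polymorphic (segregating) inversions. Passing
tests therefore demonstrate the correctness of the inference logic, not
robustness to noisy real-world reads or assemblies.

## Numerical and design choices

* Coordinates are 0-based half-open internally; printed assembly spans are
  treated as 1-based inclusive (so 9,485,167–9,486,712 is 1,546 bp) and
  conversions are explicit (`coords1to0`, `coords0to1`).
* 2La is coded fixed-inverted in *An. gambiae* for scoring; its polymorphic
  status is metadata.
* AGAP013533 is an alias of the AGAP001983-side block of the distal 2Rp
  breakpoint.
* The 2La breakpoint anchors are oriented so that the pairs syntenic in
  *Culex*/*Aedes* (AGAP007068·AGAP005778 and AGAP007069·AGAP005780) are the
  inverted-arrangement junctions, making the standard-frame junctions the
  consecutive-gene pairs (7068·7069, 5778·5780).
* Tie-breaks are deterministic throughout: reversal enumeration is
  lexicographic by `(start, end)`, Sankoff backtracks take the first
  minimum, optimal topologies are ordered by canonical Newick.
* Defaults: `minSupport = 2` pairs per call, `seedLength = 20`,
  `maxInsertFactor = 3`; unstated in the source material and conservative.
* Problem sizes used by the tests and the acceptance runs — a 4-Mb toy
  genome at 30x for breakpoint recovery, 1–8-kb junction gaps at 50x with
  ten replicates, 20 MITE replicates, 50 simulated histories at eight taxa —
  are the package's chosen desk-scale study conditions.

## Known limitations

* The arm state graph restricts internal nodes to arrangements reachable
  from the reference by valid flips; exotic histories passing through
  arrangements outside that component would be invisible (none arise for
  this complex's catalog).
* Topology search is exhaustive and therefore capped at eight taxa.
* The BFS distance oracle is capped at `n = 8`; the analytic distance has no
  cap but is only oracle-verified to `n = 7`.
* The mate-pair caller assumes unique exact mapping; with real, erroneous
  reads the support thresholds would need recalibration.
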