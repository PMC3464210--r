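# chromoPhylo

Rooted chromosomal phylogenies from fixed paracentric inversions, modelled on
the *Anopheles gambiae* species complex.

Sibling species of disease-vector complexes are often too similar, and too
introgressed, for sequence markers to resolve their ancestry. Fixed
chromosomal inversions are better characters: they rarely arise twice, they
do not introgress, and when two inversions **overlap** only certain orders of
fixation events are geometrically possible, which makes the characters
informative about direction. `chromoPhylo` implements the complete inference
chain around this idea:

* **Karyotype model** — each chromosome arm is a signed permutation
  π = (π₁, …, πₙ) of the segments between catalogued breakpoints; an
  inversion is a reversal that must cut at its two breakpoint junctions, so
  a state flip is valid in π iff a reversal exists whose cut adjacencies are
  exactly those junctions. For the overlapping 2Ro/2Rp pair this reproduces
  the constraint that 2Rop → 2Ro+p → 2R+o+p is possible while
  2Rop → 2R+op is not, in either direction.
* **Rearrangement engine** — exact signed reversal distance by the
  Hannenhalli–Pevzner breakpoint-graph formula
  *d = (n + 1) − c + h + f*, arbitrated by an exhaustive breadth-first
  oracle (agreement on every signed permutation with n ≤ 5 and 1,000 random
  pairs at n ≤ 7), plus exhaustive enumeration of minimal reversal
  scenarios.
* **Phylogeny scenarios** — exhaustive minimum-event tree search (Sankoff
  parsimony over trajectory-validated arrangement states, compiled scan of
  all 10,395 eight-taxon topologies) under alternative outgroup X-chromosome
  ancestries (X+, Xbcd, Xag), with per-inversion origin counts, outgroup
  rooting, and event replay.
* **Mate-pair detector** — inversion breakpoints called from clusters of
  uniquely mapping read pairs that map far apart in the same orientation
  (2/3/5-kb inserts, 36-bp reads), with the analytic detection limit
  `insertSize ≥ gap + 2·readLength` verified by simulation.
* **Breakpoint annotator** — arrangement calls from breakpoint-flanking gene
  adjacencies in outgroup genomes (ortholog- and alias-aware, with
  unresolved-scaffold handling), breakpoint-region arithmetic, and the MITE
  boundary procedure: repeat-copy discovery, flank-profile boundary
  definition, and target-site-duplication (TSD) length inference.
* **Synthetic data** — seeded generators for genomes, catalog realisations,
  karyotype histories on trees, mate-pair libraries and MITE insertions,
  all with machine-readable truth records.
* **Pipeline** — `runPipeline()` chains simulate → detect → encode →
  distance → phylo → report with a reproducibility manifest;
  `inst/scripts/ikit.R` exposes the same steps as shell subcommands.

## Worked example

```r
library(chromoPhylo)

## the An. merus 2R arm: overlapping inversions 2Ro + 2Rp
cat2 <- catalog2Rop()
merus <- encodeKaryotype(c(`2Ro` = "inverted", `2Rp` = "inverted"), cat2)[["2R"]]
merus
#> SignedPermutation [2R]: (1,-3,-4,2,5)
junctionAdjacencies(merus, buildSegmentMap(cat2, "2R"))[, 1:3]
#>   junction anchorLeft anchorRight
#> 1        1 AGAP001760  AGAP002933
#> 2        2 AGAP001984  AGAP003327
#> 3        3 AGAP002935  AGAP001762
#> 4        4 AGAP001983  AGAP003328
reversalDistance(merus, 1:5)
#> [1] 2

## three-scenario analysis of the whole complex
km <- gambiaeKaryotypeMatrix()
bs <- bestScenario(km, c("X+", "Xbcd", "Xag"))
bs$winner
#> [1] "Xag"
bs$scenarios[["Xag"]]
#> Scenario Xag: 10 events, 3 optimal topologies
#>   all inversions originate once
bs$scenarios[["X+"]]@totalEvents
#> [1] 11
```

The permutation `(1,−3,−4,2,5)` is the merus arrangement whose junctions
carry the gene pairs AGAP001760·AGAP002933 and AGAP001762·AGAP002935 at the
2Ro breakpoints — the arrangement two reversals away from the reference.
The scenario scan shows that only the Xag outgroup ancestry explains all ten
fixed inversions with a single origin each (10 events); the X+ and Xbcd
ancestries need an eleventh event, optimally a second origin of 2Ro. The
three optimal Xag topologies differ only in the resolution of the
quadriannulatus A/B pair, which sits at rearrangement distance zero.

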