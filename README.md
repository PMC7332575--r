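# plastomeRearr

Comparative analysis of plastid-genome (plastome) structural variation in
lineages that have lost one copy of the large inverted repeat (IR).

Typical photosynthetic angiosperm plastomes are quadripartite — a large
and a small single-copy region (LSC, SSC) separated by two identical
~25 kb inverted repeats (IR_A, IR_B). The rare lineages that lose one IR
copy tend to accumulate striking structural change: large inversions,
translocations, gene and intron losses, pseudogenes, and short
inverted-repeat (sIR) pairs that flip-flop the genome between two
isomeric configurations. `plastomeRearr` provides the complete
computational chain used to quantify this, for people studying organelle
genome evolution:

* **IR / sIR detection and excision** — exact inverted-repeat pairs,
  classed IR vs sIR by length; the redundant copy is excised before any
  comparison (`classifyIR()`, `exciseIRB()`).
* **Synteny blocks and signed permutations** — shared single-copy genes
  anchor locally collinear blocks (LCBs); each genome becomes a signed
  permutation of block labels relative to a reference, or published block
  orders are ingested directly (`buildBlocks()`, `encodePermutation()`,
  `readPermutations()`).
* **Exact reversal distance** — the Hannenhalli–Pevzner closed form
  `d = (n + 1) − c + h + f` on the breakpoint graph (cycles, hurdles,
  fortress), plus a verified optimal reversal scenario
  (`reversalDistance()`, `optimalScenario()`), with an exhaustive search
  oracle for validation (`exhaustiveDistance()`).
* **Dispersed repeats** — all maximal forward / palindromic / reverse /
  complement repeat pairs under Hamming criteria such as
  (≥30 bp, ≤3 mismatches, ≥90% identity), with an all-pairs oracle
  (`findRepeats()`, `bruteForceRepeats()`, `binRepeats()`).
* **sIR isomer evidence** — both flip-flop configurations are built and
  scored by properly-oriented read pairs whose insert (330–600 by
  default) spans an entire sIR copy (`flipIsomer()`, `mapPairs()`,
  `filterByInsert()`, `spanningSupport()`, `isomerEvidence()`).
* **Dollo loss mapping** — gene, intron and IR losses scored from
  annotation and mapped as irreversible events onto a rooted tree, with a
  brute-force minimality oracle (`charactersFromGenomes()`,
  `dolloLosses()`, `dolloOracle()`).
* **Synthetic evolution** — a seeded generator of quadripartite
  ancestors (13-block, 112-gene catalog) with scripted inversions,
  translocations, IR loss, pseudogenization, sIR insertion, a
  byte-replayable truth log, and a paired-end read simulator
  (`generateAncestor()`, `applyEvents()`, `simulateReads()`).
* **Pipeline** — `runComparison()` chains IR classification → excision →
  blocks → distances → repeats → loss mapping → isomer evidence with
  structured logging and deterministic output;
  `inst/scripts/plastome-cli.R` is a thin command-line front end.

## Worked example

The distance engine on published locally-collinear-block orders (the
reference genome's own order is the identity `1..13`):

```r
library(plastomeRearr)

perms <- list(
  Balanops   = signedPermutation(1:13),
  Lophopyxis = signedPermutation(c(1, 2, 3, 4, -6, -5, 7, 8, 9, 10, -13, 11, 12)),
  Drypetes   = signedPermutation(c(1, 13, -10, 9, -8, 6, 7, -5, -4, 3, -2, 11, -12)))

for (id in names(perms)) {
  res <- reversalDistance(perms[[id]])
  g <- distanceGraph(res)
  cat(sprintf("%-11s b=%-2d c=%-2d h=%d f=%d  d=%d\n", id, g@breakpoints,
              g@cycles, g@hurdles, g@fortress, distanceValue(res)))
}
```

```
Balanops    b=0  c=14 h=0 f=0  d=0
Lophopyxis  b=5  c=11 h=0 f=0  d=3
Drypetes    b=11 c=7  h=0 f=0  d=7
```

`b` is the breakpoint count, `c` the breakpoint-graph cycle count, `h`
hurdles, `f` the fortress flag, and `d = (n+1) − c + h + f` the minimum
number of inversions separating the genome from the reference order: the
*Lophopyxis*-type order is 3 inversions away, the shared *Drypetes*-type
order 7. A certified shortest scenario:

```r
sc <- optimalScenario(perms$Drypetes)
nrow(sc)   # 7
```

```
  step 1: reverse blocks 2..11 -> 1 2 -3 4 5 -7 -6 8 -9 10 -13 11 -12
  step 2: reverse blocks 3..3  -> 1 2 3 4 5 -7 -6 8 -9 10 -13 11 -12
  ...
  step 7: reverse blocks 11..12 -> 1 2 3 4 5 6 7 8 9 10 11 12 13
```

Each step lowers the distance by exactly one and the replay ends at the
identity. A full synthetic study — generate an ancestor, script events,
run the pipeline — looks like:

```r
anc <- generateAncestor(ancestorConfig(seed = 1, scale = 0.1), id = "ref")
ref <- exciseIRB(anc$genome, classifyIR(anc$genome, min_ir_len = 2000)[[1]])
ev  <- applyEvents(anc$genome, list(evIRLoss("B"), evGeneLoss("accD")))
evolved <- ev$genome; evolved@id <- "evolved"
runComparison(list(ref, evolved), "ref", min_ir_len = 2000)
```

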