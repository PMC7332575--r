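---
title: "Methods: plastome structural variation after inverted-repeat loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plastome structural variation after inverted-repeat loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomeRearr)
```

## The problem

Most photosynthetic angiosperms carry a quadripartite plastid genome
(plastome): a large and a small single-copy region (LSC, SSC) separated by
two identical ~25 kb inverted-repeat copies (IR~A~, IR~B~). A handful of
lineages have lost one IR copy, and those lineages tend to show unusually
many structural rearrangements — inversions, translocations, gene and
intron losses, pseudogenization. Quantifying that association requires a
chain of computations: detect and excise the redundant IR copy so that
IR-bearing and IR-lost genomes are compared over homologous single-copy
sequence; segment the genomes into shared locally collinear blocks (LCBs)
and encode each genome as a signed permutation of block labels; compute
the exact minimum number of inversions separating each genome from a
reference; enumerate dispersed repeats, which are the suspected mediators
of rearrangement; test for the two "flip-flop" isomers that a short
inverted repeat (sIR) pair can generate, using paired-end read spans; and
map irreversible losses onto a phylogeny. `plastomeRearr` implements this
chain as a reusable, fully seeded pipeline, exercised end-to-end on
synthetic plastomes whose true history is known.

## Reversal distance (the core statistic)

A genome is encoded as a signed permutation $\pi = (\pi_1, \dots, \pi_n)$
of LCB labels; the sign records strand relative to the reference, whose
own order is the identity. The distance is the Hannenhalli–Pevzner
reversal distance

$$ d(\pi) = (n + 1) - c(\pi) + h(\pi) + f(\pi), $$

where $c$ is the number of cycles in the breakpoint graph of the framed,
doubled permutation, $h$ the number of hurdles among its unoriented
components, and $f \in \{0,1\}$ the fortress indicator (an odd number of
hurdles, all of them superhurdles). The implementation builds the framed
doubling ($+x \to (2x-1, 2x)$, $-x \to (2x, 2x-1)$, framed by $0$ and
$2n+1$), counts cycles by union–find, classifies a gray edge as oriented
when its two endpoint positions share parity, groups cycles into
components by gray-edge interleaving, and identifies hurdles as unoriented
components whose positions are consecutive on the circle of all
unoriented-component positions. Permutations are treated as **linear**,
framed by $0$ and $n+1$: this convention reproduces the published
distances from the published block orders (distance 3 for the single
inversion plus block-13 relocation pattern; 7 for the shared
heavily-rearranged order), which is how the block orders were evidently
scored; a circular-genome distance is out of scope.

`optimalScenario()` emits one shortest sorting sequence by applying, at
each step, the lexicographically smallest $(i, j)$ reversal that lowers
$d$ by exactly one (such a reversal always exists by HP theory). Optimal
scenarios are non-unique; the fixed tie-break makes output reproducible,
and each emitted scenario carries its own certificate (replays to the
identity, monotone distance decrease).

Correctness is not taken on faith: `exhaustiveDistance()` is an
independent iterative-deepening search over reversal sequences, pruned
only by the cycle bound $(n+1)-c$, and the test suite checks equality on
*every* signed permutation of $n \le 5$ (4,224 cases beyond the trivial
sizes) and on 500 random permutations of $n \in \{6,7,8\}$. During
development the closed form was additionally validated against a full
breadth-first enumeration of the reversal graph for all $n \le 5$.

## Repeat finding

`findRepeats()` enumerates *maximal* repeat pairs under a Hamming
criterion (`min_len`, `max_hamming`, `min_identity`), in four classes:
forward, palindromic (= inverted, second copy compared as reverse
complement), reverse, and complement. A pair is maximal when extending it
one base in either direction (where the sequence allows) would exceed the
mismatch budget. Counting is one record per unordered occurrence pair;
nested and overlapping hits are reported as the maximality definition
dictates, so absolute counts are comparable only between tools with the
same convention — the bin *semantics*, not any published tool's tallies,
are the tested surface.

The search is exact-seed based. A window of length $\ell$ with at most
$k$ mismatches is split by them into at most $k+1$ exact runs, so it must
contain an exact match of length $\lceil (\ell - k)/(k+1) \rceil$; note
the frequently-quoted $\lceil \ell/(k+1) \rceil$ is one base too long and
would miss evenly-spaced mismatch layouts. Only seed-bearing alignment
diagonals are scanned; a vectorized triage step first discards seeds that
cannot sit inside any qualifying window, and on long diagonals only
mismatch-bounded neighbourhoods of the surviving seeds are examined.
Maximal windows on a diagonal are read directly off the mismatch
positions: with sentinels, the maximal windows are exactly the stretches
between the $i$-th and $(i+k+1)$-th mismatch. The independent test oracle
(`bruteForceRepeats()`) scans **all** diagonals and extracts windows by
prefix-sum search instead; the suite demands exact hit-set equality on
dozens of random and planted sequences.

Bases outside A/C/G/T always count as mismatches (even N against N):
conservative and deterministic.

## IR detection, excision and naming

`classifyIR()` demands exact identity between the two copies of an
inverted pair (plastome IR copies are identical; exactness avoids
ambiguous boundary calls) and separates classes by length alone: the
longest exact inverted pair $\ge$ `min_ir_len` (default 10 kb) is the IR;
everything $\ge$ `min_sir_len` (default 30 bp, overridable down to the
11 bp floor observed for plastome sIRs) is an sIR. Circular genomes are
scanned twice, once in a half-rotated frame, so origin-spanning pairs are
found; a wrapped copy is reported with `end > genomeLength`.

Which copy is "IR~B~" is a positional convention: `exciseIRB()` removes
the copy that immediately precedes the shorter single-copy region. Under
this convention the excised reference reads its 13 blocks in ascending
order, consistent with published block tables in which the block covering
the SSC continues into the *retained* IR copy. Dispersed-repeat scans and
block construction run on IR-excised sequences, the standard
normalisation for aligning IR-bearing against IR-lost plastomes.

## Synteny blocks and encoding

`buildBlocks()` is a desk-scale stand-in for whole-genome-alignment LCB
finding: genes present exactly once in every genome act as signed
anchors; a boundary between reference-adjacent anchors is cut when any
genome fails to carry the two anchors adjacently in consistent relative
orientation (circular adjacency included). IR-duplicated genes are
excluded from anchoring — one copy may survive IR loss, which would break
the 1:1 mapping around the rRNA operon. Consequences, documented rather
than hidden:

* the segmentation is the **coarsest** one consistent with witnessed
  breakpoints — a boundary no compared genome breaks is invisible;
* anchor-free sequence (one of the 13 default blocks is a purely
  intergenic region) is absorbed into the preceding block, the genome
  head into the first block;
* exact reproduction of a published block table on real accessions
  therefore uses the import path (`readBlockTable()`,
  `readPermutations()`), not re-derivation.

Encoding rotates circular genomes so the block labeled 1 comes first and
reads the circle in the orientation making that block positive — the
convention under which published per-genome block orders all begin
with "1". Ties when a run could extend either neighbouring block do not
arise under the cut-based construction; gene-free spans attach leftward
for determinism.

## Synthetic evolution (what the generator does and does not emulate)

`generateAncestor()` assembles a circular `LSC | IR_B | SSC | IR_A`
genome. Defaults emulate the canonical plastome: 86 kb LSC, 16 kb SSC,
26.7 kb IR per copy (~155 kb total, inside the 120–160 kb envelope of
photosynthetic angiosperms), and a 112-gene catalog laid out in 13
blocks, with 4 rRNA, 7 tRNA and 5 protein-coding genes duplicated in the
IR. Intergenic spacers are i.i.d. uniform random DNA drawn from a
configurable length range and then rescaled so each compartment hits its
configured length exactly; protein genes are clean ORFs (ATG, no internal
stops, terminal TAA) with annotated exon/intron structure for the
intron-bearing genes. Because every base outside scripted constructions
is random, the only repeats in the genome are the ones planted
deliberately — planted-repeat tests are exact, not statistical.

`applyEvents()` applies inversions, IR loss, gene loss, intron loss,
pseudogenization (a real in-frame TAA early in the coding sequence,
recorded in the feature notes), sIR insertion (a fresh random segment
plus its reverse complement at a second position) and translocations,
left to right, re-validating coordinates after each event and refusing
events that would split a feature. Every event resolves to primitive
sequence operations recorded in a truth log; replaying the log on the
ancestor reproduces the evolved genome byte-for-byte, which is the
anchor for all recovery tests.

The generator does **not** emulate: nucleotide substitution along
branches, codon usage, indel sequencing errors, IR boundary
expansion/contraction, or repeat-mediated (as opposed to scripted)
rearrangement. Passing recovery tests therefore demonstrate correctness
of the *computational chain*, not robustness to alignment noise on real
data.

`simulateReads()` draws fragment starts uniformly on the circle and
insert lengths from a truncated normal; mates face inward (FR) and the
insert is the outer fragment length, the SAM `TLEN` convention, giving
the insert-size filter an exact semantics. All randomness flows from
explicit integer seeds through a private RNG stream; the same seed gives
byte-identical FASTQ.

## Isomer evidence

A pair of sIR copies can mediate flip-flop recombination, inverting the
segment strictly between them (`flipIsomer()`, an involution that leaves
the copies themselves untouched). Read-pair support for a configuration
is formalized as: both mates uniquely and exactly placed, inward-facing,
insert inside the window (inclusive on both ends; default 330–600, the
published filter), and the entire repeat copy strictly inside the inner
gap between the mates — one mate ends before the copy starts, the other
starts after it ends. Only such pairs anchor the flank configuration
unambiguously; a mate overlapping the repeat is compatible with both
isomers. An isomer is "supported" at `min_support = 1` — existence, as in
the visual-inspection protocol this replaces — and the evidence table
reports the per-copy counts so stricter thresholds can be applied.

Geometry matters here: spanning a repeat of length $s$ requires an insert
of at least $s + 2r + 2$ for read length $r$. With the 271 bp sIR and the
330–600 window this is feasible for the ~90–100 bp reads of
genome-skimming libraries but marginal at 150 bp, so the isomer studies
in the tests simulate 90 bp reads at insert 450 ± 50 — the regime in
which the published confirmation operated.

## Dollo loss mapping

Gene presence is scored from annotation: state 1 only for an intact
`gene` feature (pseudogenes score 0 together with physical losses, the
joint convention of loss surveys; the narrative distinction is preserved
in the feature notes), intron characters by presence of the intron
feature. With the root fixed to "present" (the outgroup retains all
features), the minimal irreversible-loss explanation places one event on
the stem of each maximal clade whose scored leaves are all 0 and which
contains at least one 0. Leaves scored `?` are compatible with either
state: they never create, forbid, or split an event. The pinned
degenerate case — every leaf 0 — maps a single event onto the root
branch spanning all taxa. `dolloOracle()` independently enumerates
event-branch subsets of increasing size under the irreversibility
constraints; the suite checks equality on hundreds of random eight-leaf
trees.

## Numerical and design choices

* **Coordinates.** 1-based, closed intervals everywhere in R, matching
  Bioconductor containers and the GFF3 dialect on disk; FASTA/GFF3/TSV
  round-trips are identity and tested as such. Circular features wrapping
  the origin are stored as two rows sharing a `feature_id`.
* **Repeat report bins.** 30–60, 60–100, 100–500 bp and ≥1000 bp,
  low-inclusive; the conventional bin set leaves 500–999 bp unassigned,
  which is reported as an explicit `500-1000bp` column rather than folded
  silently into a neighbour. Bin counts plus the sub-30 remainder always
  sum to the total.
* **Scenario tie-break.** Lexicographically smallest distance-reducing
  reversal; published scenario *lengths* are unique, the scenarios
  themselves are not.
* **Insert window.** "Between 330 and 600" is read inclusively; the
  boundary semantics are pinned by a test.
* **Problem sizes.** The test suite runs the generator at `scale = 0.1`
  (a ~15.5 kb ancestor with the full 13-block, 112-gene catalog and a
  2.7 kb IR), 100 seeded inversion scenarios of up to six events, the
  full $n \le 5$ oracle sweep plus 500 random $n \in \{6,7,8\}$ cases,
  50-sequence repeat-oracle sweeps, 6,000-pair isomer simulations and
  200-tree Dollo sweeps — sizes chosen so the full chain, not a
  truncation of it, is exercised on every run.

## Known limitations

* The anchor-based block builder cannot recover boundaries that no
  compared genome breaks, nor anchor-free blocks; published segmentations
  are inputs, not targets, on real data.
* Reversal distance is computed for a single linear chromosome;
  translocation/fission multichromosomal models and DCJ are out of scope.
* The internal mapper is exact-match only, which is the right tool for
  error-free synthetic reads; real noisy libraries should be mapped
  externally and ingested as alignments.
* `findRepeats()` is tuned for desk-scale and IR-excised plastome-scale
  sequences; highly repetitive megabase genomes would need a suffix-based
  engine.
* Fortress permutations ($f = 1$) require more blocks than plastome LCB
  tables exhibit; the fortress branch follows the published theory and is
  exercised only insofar as the random oracle sweeps reach it.
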