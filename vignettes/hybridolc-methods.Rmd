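---
title: "Compressed-domain hybrid assembly: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compressed-domain hybrid assembly: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hybridolc)
```

## The model

Third-generation long reads carry 15–40 % base-level error but are long
enough to resolve genome structure. The central assumption of this package
is that the two error classes need opposite treatment: *base-level* errors
can be deferred to a final consensus, while *structural* errors (chimeric
reads) must be found and removed before any graph is built, because a
single false join tangles the overlap graph out of proportion to its
frequency.

Accurate short-read (de Bruijn) contigs provide the coordinate system that
makes this cheap. Each long read is lossily compressed to the ordered,
oriented list of contigs that anchor on it; overlap detection, cleaning and
graph construction then operate on sequences that are shorter by roughly
three orders of magnitude, where a full Smith–Waterman costs microseconds.
Only the final layout/consensus stage touches nucleotides again.

## Stage-by-stage assumptions and parameters

### Anchoring (`build_unique_kmer_index`, `anchor_reads`)

* `k = 17` (bases). Large enough that a random 17-mer essentially never
  repeats in genomes up to mammalian size, small enough that a 15 %-error
  read still matches an exact 17-mer every ~16 bases
  ($0.85^{17} \approx 0.063$).
* Only *globally unique* canonical k-mers are indexed. K-mers repeated
  within one contig are excluded too: they are positionally ambiguous even
  though the contig is unambiguous.
* An anchor is reported when the per-contig hit count reaches
  `max(min_support, ceiling(adaptive_frac * contig_length))` with
  `min_support = 2` (one spurious hit must never anchor a tiny contig).
  `adaptive_frac` trades sensitivity for specificity within its calibrated
  range 0.001–0.02. The package default is the mid-range 0.008, but **low
  coverage data (10–20x) should use ~0.002**: with contigs of tens of
  kilobases, 0.008 × contig length demands several kilobases of
  read–contig overlap, and reads spanning contig junctions — the only
  reads that carry layout information — stop anchoring both sides. All
  acceptance-scale tests in this package run at 0.002 for exactly this
  reason.
* Anchor orientation is the majority vote of the hit strands; a tie drops
  the anchor (a wrongly oriented anchor corrupts the graph more than a
  missing one). The anchor position is the median supporting hit, and the
  first/last exact hit pairs (read position, contig offset) are retained —
  they later give base-exact splice points for contig patching.
* A compressed read and its reverse complement are equivalent; the
  canonical representative is the lexicographically smaller
  (contig, orientation) sequence. Every stage afterwards operates on
  canonical forms, which is what makes the whole pipeline exactly
  strand-symmetric (assembling reverse-complemented input reproduces the
  assembly up to reverse complement, byte for byte).

### Compressed-domain alignment (`align_compressed`)

Match scores are the involved contig lengths (`by_contig_length`, default)
or the shared k-mer support (`by_kmer_support`); mismatch and gap penalties
default to −(median contig length)/4 so that penalties are commensurate
with length-weighted matches. `min_overlap_score = 150` length-weighted
units gates usable overlaps.

Relation classification (containment vs dovetail) deliberately avoids
traceback tie-breaking: the code computes, besides the local optimum, four
constrained optima (each read fully consumed; alignment reaching a's end
and b's start, and the mirror) and declares a relation when its constrained
optimum *attains* the local optimum. This makes decisions independent of
which co-optimal alignment a traceback happens to visit, and exactly
reproducible by an independent enumeration oracle — the form in which the
test suite checks it.

### Cleaning (`clean_reads`)

Cleaning runs on uncollapsed reads (identical twins are genuine mutual
confirmations) and makes two passes:

1. *Spurious anchors.* An anchor is kept if at least `min_confirm`
   neighbour alignments match it. A neighbour's alignment only counts when
   it matches ≥ 2 target anchors (1 for single-anchor targets): a lone
   shared identifier is mere co-occurrence of a contig that lives elsewhere
   in the genome — which is exactly what a false anchor attracts — not a
   confirming alignment. When an *end* anchor is removed, the read's frame
   interval is trimmed back to the outermost confirmed hit: sequence beyond
   the last confirmed anchor, with an unconfirmed anchor out there, is
   suspect — it is precisely how a chimeric tail whose far side carries a
   single anchor presents itself. Many chimeras are therefore neutralized
   already in this pass (their unsupported far side is excised) rather
   than by an explicit breakpoint, which is why the chimera acceptance
   property is stated as "no surviving compressed read joins the two
   loci", not as a split-verdict count.
2. *Chimeras.* For each junction between consecutive anchors, a neighbour
   *crosses* the junction only if it matches the two flanking anchors
   consecutively on both reads (a match on both sides with extra structure
   in between is a disagreement). A breakpoint is called when fewer than
   `min_cross` neighbours cross and the left- and right-supporting
   neighbour sets are disjoint; the read is split there, fragments keep
   the bases out to their outermost supporting k-mer hits, and fragments
   with fewer than two anchors are dropped.

`min_confirm` (= `min_cross`) defaults to 1 and is raised to 2 when the
estimated long-read coverage exceeds ~10x. The second unit matters: a pair
of chimeric reads that happen to fuse the same contig pair would otherwise
shield each other from detection.

Two limitations are inherent and documented rather than hidden: a chimera
whose two loci fall inside the *same* contig compresses to a single anchor
and is invisible in the identifier domain (with ~10 contigs per 100 kb this
is ~10 % of chimeras); and at ~1x coverage, where no read is confirmable by
another, cleaning legitimately discards essentially every multi-anchor
read — the documented cost of the approach, which is why it slightly
raises the coverage requirement.

### Best overlap graph (`remove_contained`, `best_overlaps`, `simplify_graph`)

Round 1 removes contained reads (mutual containments keep the smaller id).
Round 2 keeps, per node side (B/E in the bidirected convention), the
highest-scoring dovetail; an edge is materialized when it is the best for
at least one side and within `mutual_frac = 0.95` of the best on the other
— pure mutual-best fragments low-coverage data, pure one-sided-best
creates branch conflicts. Ties break on matched identifier count, then
partner id, so the graph is deterministic.

Simplification clips dead-end arms of ≤ `tip_len = 3` nodes at branch
points (when all arms at a branch are short dead ends, the best-scoring
one survives — two chain termini meeting head-on must not erase each
other) and pops bubbles of ≤ `bubble_len = 5` nodes by total overlap
score, to a fixpoint. Fully circular chains are emitted once with a
circularity flag.

### Layout and consensus (`layout_backbone`, `polish_backbone`)

Junction offsets between consecutive backbone reads are the median, over
shared anchors, of the offset implied by the paired (read position, contig
offset) supporting hits. When two reads share no raw bases, the bridging
contig fills the gap, spliced at each read's outermost *exact* k-mer hit —
so an error-free contig yields a base-exact patch. The same principle
extends backbone ends with terminal contig sequence: genome ends always
lose half a read length of long-read coverage, and the contig is the
evidence that covers them.

The consensus builds a sparse k-mer graph over the draft (a node every
`g = 2` bases labelled by the local `k_c = 2`-mer; node identity =
position + label). The draft threads it with weight 0 (weight 1 on
contig-patched segments: contig bases are coverage-1 evidence), each
aligned read adds +1 per edge (FASTQ qualities, when meaningful, can
replace the unit increments), edges are reweighted
`w' = w − t·cov(position)` with `t = 0.2`, and the heaviest source-to-sink
path — computed by dynamic programming over the layered DAG, with a fixed
edge order for tie-breaking — is read out through the edge sequences.
`consensus_rounds = 2` by default: the first round aligns reads against a
~15 %-error draft and converges near 99.4 % identity; re-aligning against
the round-1 consensus sharpens placements and gains another ~0.1–0.2 %.

The read-to-backbone aligner is a built-in seed–chain–extend: unique
draft 11-mers, a dominant-diagonal band (half-width 500), longest
increasing subsequence chaining, splitting at gaps > 2 kb, global
alignment of the seed gaps (unit scores, fixed tie order) in C++, and an
identity floor of 0.5 (two independent 15 %-error sequences agree at
~0.72). External aligners can be plugged in through
`read_sam_alignments()`.

## What the simulator emulates — and what it does not

`simulate_genome` / `simulate_contigs` / `simulate_reads` produce a uniform
random genome (optionally with planted, degraded repeat families), contigs
cut at Poisson gap positions (default 1 gap / 10 kb, lognormal gap lengths
with ~200 bp median, error-free sequence — short-read contigs are treated
as accurate), and reads with lognormal lengths (mean ~8 kb), uniform
placement, random strand, independent per-base substitution / insertion /
deletion errors (default 5 % each, the ~15 % PacBio regime) and optional
single-junction chimeras joining two independently sampled loci.

Not emulated: sequence-context error biases (homopolymer indels),
coverage biases, quality-score structure, multi-junction chimeras, and
repeat structure beyond planted families. A green structural-recovery test
therefore establishes that the algorithmics are correct under the stated
error model, not that the pipeline is robust to every real-platform
artifact; conversely the oracle-equivalence tests (Smith–Waterman,
containment, heaviest path) are model-free.

## Numerical and degenerate-input choices

* All internal coordinates are 0-based k-mer starts; file formats are
  1-based where their conventions demand it.
* Scores are doubles; relation classification compares constrained optima
  with an absolute 1e-9 epsilon (scores are sums of the same addends, so
  this only guards float association).
* Empty compressed reads are legal everywhere and dropped at collapse.
* Reads shorter than k, reads with zero anchors, pools with zero usable
  alignments, and drafts shorter than `k_c + g` all degrade to no-ops with
  warnings rather than errors.
* Every stage is deterministic given inputs and configuration; the only
  randomness in the package lives in the simulator, seeded explicitly.

## Known limitations

* Same-contig chimeras are undetectable in the compressed domain (above).
* Near-identical long repeats collapse to shared identifiers; truly
  unresolvable repeats terminate backbones at branch nodes rather than
  being resolved by search, by design.
* The consensus cannot restore sequence in regions covered by neither
  reads nor a contig; such regions stay as drafted.
* Pure R + small C++ kernels: comfortable to ~1 Mb genomes at 20x on one
  core (minutes); it is an algorithmic reference implementation, not a
  production assembler for mammalian genomes.
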