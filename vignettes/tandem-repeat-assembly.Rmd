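---
title: "Tandem repeat restoration from read depth: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tandem repeat restoration from read depth: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tandemasm)
```

## The model and its assumptions

tandemasm builds a de Bruijn graph of dimension $k$: vertices are
$(k{-}1)$-mers, edges are observed $k$-mers carrying an integer weight $w$
(the $k$-mer's count in the reads). The statistical model assumes $N$
error-free reads of identical length $L$ drawn uniformly from a circular
genome of length $G$. Under these assumptions a unique $k$-mer has expected
weight $N(L-k+1)/G$, a $k$-mer inside a tandem array of length $n$ with
motif length $d$ has expectation inflated by $\Delta/d$ with
$\Delta = n-k+1$, and the weight is Poisson. Multiplying by
$p = G/(N(L-k+1))$ and rounding half-up converts weights into per-genome
copy numbers; for read depth $c = NL/G \ge 100$ the normalized repeat
weight is approximately $\mathcal N(\Delta/d,\sqrt{\Delta/d})$, and the
planner `required_coverage(q, k, L, n, d)` inverts this to the depth at
which a repeat edge resolves its copy number with confidence $q$.

Every assumption is violated a little in practice, and the design choices
below are mostly about keeping the copy numbers right when they are.

## Normalization under sequencing errors

With substitution rate $e$, only $(1-e)^k$ of read $k$-mers are error-free
($\approx 0.58$ at $e = 0.01$, $k = 55$). Cleaning removes the erroneous
edges but cannot restore the lost weight, so the literal factor
$G/(N(L-k+1))$ under-normalizes by the same $\approx 42\%$ and every copy
number rounds low. The pipeline therefore evaluates the same identity with
the *effective* $k$-mer count: $p = (\text{strands} \times G) / W$, where
$W$ is the total edge weight of the cleaned graph. On error-free input
$W = N(L-k+1)$ per strand and this *is* the model factor; with errors it
self-corrects, because numerator and denominator shrink together. The
exported `normalization_factor()` keeps the textbook form.

By default each read contributes $k$-mers of both its sequence and its
reverse complement (`single_strand = FALSE`), so the graph represents both
genome strands and the genome length entering $p$ is $2G$. Strand-duplicate
contigs are dropped after traversal (exact reverse-complement matches
only; with errors the two strand assemblies may differ slightly and both
are kept — they are scored identically by the evaluator).

`genome_size` should be supplied when known. The fallback estimate
(distinct $k$-mers, halved in double-strand mode) is standard for
repeat-poor genomes but biased low by construction on repeat-dense toys,
since all copies of an array collapse onto $d$ distinct $k$-mers.

## Cleaning parameters

* **Low-weight cutoff** — `max(2, round(0.1 × modal weight))`, where the
  modal weight is read off the $k$-mer spectrum past its error peak
  (`weight_spectrum_mode()`): find the first valley after weight 1, take
  the mode above it. The cutoff is applied to the count table before the
  graph is materialized (identical result, far less memory: at 1%
  substitutions the weight-1 error $k$-mers outnumber true ones several
  times over).
* **Tips** — dead-end unbranched paths of at most $2k$ edges hanging off a
  branch vertex, removed when their minimum weight is below 0.2 times the
  strongest competing edge. Velvet-style conventional values; at the
  coverages this model requires, the cutoff does almost all the work and
  tip/bubble removal is belt and braces.
* **Bubbles** — two vertex-disjoint unbranched paths of at most $2k$ edges
  joining the same ordered vertex pair; the lighter path is deleted and its
  minimum edge weight added to every surviving edge (ties: the
  lexicographically smaller path spelling survives). Only simple bubbles
  are handled; nested ones resolve by fixpoint iteration.

Order: build → clean → normalize → balance → traverse. Cleaning must
precede normalization because $W$ must count only trusted $k$-mers.

## Loop detection and balancing

A tandem array appears as a cycle attached to the rest of the graph by
exactly one external in-edge and one external out-edge: one cycle vertex
(entry) has two in-edges, one (exit) has two out-edges, all others are
1-in/1-out. Cycles with any other degree pattern — e.g. a motif that also
occurs elsewhere in the genome, adding a second entry — are rejected and
left alone; interspersed repeat families are out of scope.

Balancing proceeds per loop: each branch is first equalized to its rounded
median weight (robust to a single misrounded edge; the choice of median
over mode or minimum is a judgement call — any of them is compatible with
a single deviant edge changing). Then the branch with more edges keeps its
weight and the other receives the unique uniform weight that zeroes the
signed degree (in-weight minus out-weight) of the entry and exit given the
external edge weights; on ties the exit→entry (back) branch is adjusted,
since it carries the $m-1$ return traversals and is the natural free
variable. If the external in- and out-weights disagree or the solution
would be negative, the loop is left unchanged and a diagnostic recorded
(`loop_report`). Note the body/back copy numbers are $m$ and $m-1$ — or
swapped in roles when the array length is not a multiple of $d$; the
balancing equations handle both because they only enforce degree zero.

## Traversal

Contigs are generated by a weight-consuming walk: append one base per
edge, decrement the edge, remove it at zero. A vertex is *unambiguous*
when each side (in/out) has at most one edge, or exactly two edges of
which exactly one has a **simple return path** — a directed path of
positive-weight edges from the edge's target back to its source whose
cycle contains at least one vertex with two in-edges and one with two
out-edges. At an unambiguous 2-out vertex the return-path edge is taken
while it has weight left, the other afterwards; that is what spools the
motif out $m$ times. Arriving at an ambiguous vertex closes the contig and
queues the vertex as a new start. Start vertices are the in-degree-0
sources, lexicographically; components without one (circular genomes)
start at their lexicographically smallest vertex. All tie-breaks are
lexicographic, making output deterministic.

Two choices here deserve justification:

* **Static classification.** Ambiguity and return paths are computed once,
  on the pre-traversal graph. Re-deriving them on the residual graph
  mid-walk breaks the worked 4-mer example: after the first pass around
  the loop the entry vertex has lost its consumed external in-edge, the
  cycle no longer shows a branching vertex, and the loop contig would be
  truncated after a single copy.
* **Bounded return-path search** (`max_return_depth`, default 1000
  edges). On a circular genome *every* edge lies on the genome-scale
  cycle, so an unbounded search finds a "return path" for both edges of
  every repeat junction and declares them ambiguous — which would
  fragment exactly the circular-genome case the method is built for.
  Tandem loops have at most $d$ edges (≤ 500 in all benchmark designs),
  while genome cycles have thousands; 1000 separates the two regimes by an
  order of magnitude on both sides. Genomes shorter than the bound with
  repeats longer than it are outside the supported regime.

## What the simulator emulates, and what it does not

`make_reference()` builds spacer+array+spacer… references with i.i.d.
uniform random spacers and motifs (the benchmark design: motifs of
100–500 bp repeated 2–5×, 1000-bp spacers, 42 kb total).
`simulate_reads()` draws fragment starts uniformly (wrapping on circular
references), fragment lengths from a rounded normal truncated at $2L-1$,
takes mate 1 from the 5′ end and mate 2 reverse-complemented from the 3′
end, applies per-base substitutions (default 1%) and, when enabled, indels
at $10^{-4}$ per base. Qualities are constant Q40: the assembler never
reads them, and no attempt is made to reproduce platform error profiles,
GC bias, quality-dependent errors, or chimeric fragments. A green
simulation test therefore establishes correctness of the depth arithmetic
and graph algebra under idealized noise — not robustness to real
instrument artifacts.

Benchmark references are simulated as **circular** even when only one
array is planted: the model assumes uniform read positions over a circular
genome, and on a 2.6-kb linear toy a 1250-bp insert concentrates mate
coverage mid-genome (both mate windows overlap only there), inflating the
array's apparent depth by up to 2× — a desk-scaling artifact, not a
property of the method. On the full 42-kb design the linear edge effect is
negligible.

## The coverage planner is a per-edge statement

`required_coverage()` gives the depth at which *one* repeat edge's
normalized weight resolves the copy number with confidence $q$, under the
model's idealization that $k$-mer counts are independent Poisson draws
(the "$k$-spectrum" world, where reads *are* $k$-mers). Two things erode
it in realistic runs: a whole loop needs all ~$d$ of its edges intact, so
structural detection needs far more than per-edge confidence (a single
weight-1 edge rounding to zero punches a hole in the cycle); and reads of
length $L$ carry $L-k+1$ consecutive $k$-mers, so neighbouring edge
weights are block-correlated and branch medians average fewer effective
observations than they appear to. The property suite checks the guarantee
in the regime where it holds — branch-median copy estimates with $L$ close
to $k$ — and the benchmark experiments run at 150–300×, far above the
planner's minimum, which is also what the model's own $c \ge 100$ regime
note demands. The planner's printed $k/(L-k+1)$ prefactor is implemented
verbatim; a derivation from the normalized-weight variance would suggest
$L/(L-k+1)$, and the difference is part of why the planner under-delivers
at $k \ll L$.

The model's rate $\lambda = NL(L-k+1)\Delta/(Gkd)$ (which carries an extra
$L/k$ relative to the plain expectation) is exposed as the diagnostic
`poisson_lambda()`; normalization never uses it, only the reciprocal
identity above — this keeps the pipeline self-consistent while preserving
the printed formula.

## Numerical choices and degenerate inputs

* Rounding is always half-up, $\lfloor x + 0.5 \rfloor$ — never banker's
  rounding (2.5 → 3).
* Reads containing `N` are split at the `N`s; fragments shorter than $k$
  are dropped.
* Empty input files parse to empty read sets; an all-short read set is an
  error with a diagnostic.
* Contigs shorter than $k-1+1$ bases are still emitted; the
  `--min-contig-length` filter trims reports only, never the FASTA.
* The repeat evaluator counts motif repetitions as maximal-tandem-run
  length divided by motif length, maximized over cyclic rotations of the
  motif (assemblies enter arrays at arbitrary phase) and, when scoring,
  over the motif's reverse complement. Counts are rational: a run ending
  mid-motif yields a fractional tail, and a flanking base that happens to
  extend a rotated phase can push a planted integer array to, e.g.,
  5.004 — benchmark aggregation rounds to the nearest integer.

## Known limitations

Unitig mode only (no paired-end scaffolding, no gap filling); exact-match
repeat evaluation; interspersed and nested repeats unresolved; no GC-bias
correction of depth; coverage below 100× triggers a warning but not an
abort, and copy numbers from such runs should not be trusted.
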