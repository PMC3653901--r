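---
title: "Reconstructing polyploid ancestors by DCJ genome aliquoting"
author: "DCJAliquot maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing polyploid ancestors by DCJ genome aliquoting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DCJAliquot)
```

## The problem

Many extant genomes descend from an ancient polyploidisation: an `r`-way
whole-genome duplication (WGD) copied every chromosome `r` times, after
which rearrangements (inversions, translocations, fusions, fissions)
scrambled the gene order.  The *genome aliquoting problem* asks, given the
extant gene order `G_obs` in which every gene family has exactly `r`
members, for a *perfectly duplicated* genome `G_dup` — `r` interchangeable
copies of a single-copy genome `G_anc` — minimising the rearrangement
distance to `G_obs`.  The case `r = 2` is genome halving; no efficient
exact algorithm is known for general `r`, so DCJAliquot implements a
greedy heuristic that minimises the distance locally.

Distances are measured in the double-cut-and-join (DCJ) model: one
operation cuts two adjacencies (junctions between consecutive genes,
represented as unordered pairs of gene *extremities* — heads, tails, or
caps at the ends of linear chromosomes) and rejoins the four loose ends
differently.  DCJ subsumes inversion, translocation, fusion, fission and
block interchange at unit cost.  For two genomes with the same labelled
gene content the distance has the closed form `d = N - (C + I/2)`, where
`N` counts genes and `C` and `I` count the alternating cycles and odd
paths of the adjacency graph; `dcjDistance()` implements exactly this and
is certified in the test suite against breadth-first search over the full
DCJ operation set on small genomes.

## The data structures

`partialGraph()` ("graph B") has one vertex per extremity of `G_obs` and
one black edge per adjacency, so it is a perfect matching on the
extremities.  `contractGraph()` ("graph A") merges all extremities of one
extremity family (for example, every copy of the head of family 7) into
one vertex; parallel edges collapse into a single edge with a
*multiplicity* and a provenance list recording which copy pair produced
each unit.  In a perfectly duplicated genome every contracted edge would
have multiplicity `r`, so an edge of multiplicity above one (*strong*) is
good evidence for an ancestral adjacency, while multiplicity-one (*weak*)
edges individually prove nothing.

## The heuristic

The reconstruction `H` starts empty and the solver iterates two steps,
then post-processes:

1. **Strong adjacencies.**  A maximum-weight matching (weights =
   multiplicities) over the strong edges of graph A fixes a batch of
   ancestral adjacencies.  For each matched pair `(u, v)` the engine must
   decide *which copies* of `u` and `v` to join.  It searches graph A for
   a set of edge-paths from `u` to `v` — maximising the number of paths
   up to `r`, then minimising total length — subject to four conditions:
   paths start and end with black edges; paths alternate colours at
   matched vertices; no edge is used beyond its multiplicity; unmatched
   vertices are interior to at most one path, at most once.  Each
   odd-length path closes an even black cycle and contributes one
   inferred adjacency from its terminal copy pairs; even-length paths are
   crossed in pairs.  The three edges around each inferred adjacency are
   then contracted into a new black edge, so second-order evidence
   accumulates in graph A as the reconstruction proceeds.  The path
   search is solved exactly as a unit-augmenting minimum-cost flow
   (vertex splitting for the disjointness condition, a two-node colour
   expansion at matched vertices, Dijkstra with potentials), and the test
   suite certifies it against exhaustive path-set enumeration.

2. **Weak adjacencies.**  When no strong edge remains, every vertex pair
   within graph-A distance `depth` (default 1) is scored by
   `W_p = alpha * N_p + (1 - alpha) * C_p` with `alpha = 0.5`, where
   `N_p` is the path count above and
   `C_p = sum(floor((L_i + 1) / 2)) / sum(L_i)` measures alternating
   cycles gained per edge cost.  On a single black cycle of length `L`
   this reproduces the three halving cases `(L+2)/2L`, `L/2L` and
   `(L+1)/2L`, which order the preferred pair choices for even and odd
   cycles.  The best pair is matched and processed exactly as in step 1,
   after which control returns to step 1 because new strong edges may
   have formed.

3. **Linearisation.**  `H` may contain circular chromosomes.  Every
   family-level adjacency of a circular component has exactly `r`
   concrete occurrences, and a DCJ applied to all `r` occurrences at once
   (merging into a linear chromosome group, or cutting into telomeres)
   always leaves a cover that splits into `r` identical copies — even for
   "wound" covers in which fewer than `r` physical circles wind around
   the quotient cycle.  Merges that do not increase the distance are
   preferred, then free splits, then the least-increase candidate.

### Choices the publication leaves open

Several micro-decisions materially affect the result; DCJAliquot fixes
them as follows and treats them as part of its own design:

* **Tie handling.**  Score ties in step 2 are frequent.  Pairs that
  would close a circular chromosome (i.e. both vertices already lie in
  one connected component of the growing reconstruction, tracked by
  union-find) are held back unless nothing else scores, because a closed
  circle costs a linearisation operation later; gene-gene pairs are
  preferred over telomere (cap) pairs; finally the solver runs the whole
  pipeline under both the ascending and the descending orientation of
  the remaining lexicographic tie and keeps the reconstruction with the
  smaller distance.  This portfolio never worsens the result and cannot
  spoil halving optimality, since the better of two valid candidates is
  reported.
* **Strong edges that close circles** are likewise deferred to later
  rounds (they frequently stem from coincidental parallel adjacencies
  created by the rearrangement process, not from the ancestor).
* **Leftover copy pairs.**  When fewer than `r` paths exist, the
  remaining copies are paired so that the contracted edge lands on the
  best-supported family adjacency, falling back to ascending copy IDs.
  An unpaired even path keeps its own terminal copies, which still
  realises its black cycle.
* **Exhausted evidence.**  Vertices that end up with nothing but
  self-loop evidence are paired with each other (closing their
  self-loops into an alternating cycle beats creating telomeres), the
  odd one out with the cap.  Cap bookkeeping consumes cap copies
  individually, while the cap vertex itself persists; a fresh
  null-chromosome cap pair is spawned if telomere pairing runs out of
  cap copies.
* **Final polish.**  Copy subscripts are arbitrary labels, but the
  labelled distance depends on them, so a greedy sweep relabels
  contiguous segments of quotient families between copy pairs while the
  distance strictly improves.  A second hill-climb explores family-level
  DCJ moves applied symmetrically to all `r` copies (rejecting moves
  that would create circular chromosomes).  Both only ever accept strict
  improvements, preserve perfect duplication and linearity exactly, and
  terminate; they implement the "locally minimises the distance" part of
  the method.

All tie-breaks are deterministic, so identical inputs and parameters give
identical outputs.

## The simulator

`simulateDataset()` generates the study conditions used throughout the
package's validation: the ancestor is the identity family order `1..n`
broken into `m` chromosomes at uniformly chosen breakpoints with `m`
uniform on `[1, m0]`; `wgd()` makes `r` copies with copy IDs `1..r`; and
`applyRandomDcj()` applies `D_N` DCJ operations, with `D_N` uniform on
`[1, r*n]`.  Each operation draws two distinct adjacencies (telomeric
included) uniformly and one of the two rejoinings uniformly; candidates
that would create a circular chromosome are rejected and redrawn, so the
simulated genomes stay linear.  Null (cap–cap) adjacencies are legal
intermediates — they are what makes fusion and fission expressible in the
capped model — and are dropped when the genome object is rebuilt.  Each
data point derives its own RNG stream from the master seed and the point
index.

What the simulator does *not* emulate: gene gains and losses (all family
sizes stay exactly `r`; the method cannot handle unequal sizes), unequal
rates across chromosomes, segmental duplications, or any sequence-level
signal.  Passing the simulated checks therefore says nothing about
ortholog-assignment errors or missing genes in real data.

## Problem sizes and numerical choices

The bundled validation works at these scales, chosen to exercise the
method well inside a routine desktop run: the headline simulation study
uses 150 data points with `n = 100` families, `m0 = 2` and `r = 3`
(`runStudy()`), on which the inferred distance tracks the simulated
distance closely below a relative distance of 0.4 and underestimates it
beyond — the expected parsimony behaviour, since far beyond that point
shorter explanations than the simulated history exist.  Oracle
certification runs at tiny sizes where exhaustive enumeration is
possible: breadth-first search for the distance (4 genes), brute-force
path-set enumeration (graphs of up to 8 vertices, multiplicities up to
3), and exhaustive minimisation over every perfectly duplicated candidate
for halving instances with up to 4 families.  Score comparisons use a
`1e-9` tolerance before the deterministic tie-break; all other arithmetic
is integer.

## Limitations

The solver is a greedy heuristic: on rare mid-divergence instances it can
land in an alternative reconstruction one or two operations worse than
the simulated history, and the halving case is provably optimal only in
the regime where graph A decomposes into clean black cycles.  Runtime
grows with the number of weak-adjacency rounds, which dominate beyond a
relative distance of about 0.5.  Gene families of unequal size are
rejected rather than approximated.

## A worked call

```{r example}
set.seed(7)
anc <- randomSingleCopyGenome(20, 2)
gobs <- applyRandomDcj(wgd(anc, 3), 15)
res <- aliquot(gobs, 3)
res
dcjDistance(gobs, wgd(anc, 3))   # simulated distance for comparison
```
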