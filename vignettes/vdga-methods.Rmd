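---
title: "Aligning protein families with a vertical-decomposition genetic algorithm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning protein families with a vertical-decomposition genetic algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdga)
```

## The problem and the approach

Progressive alignment — build a guide tree, then align sequences and
profiles in the tree's post-order — is fast but greedy: a gap placed early
is never revisited, so the result is a local optimum of whatever objective
one cares about. `vdga` wraps a genetic algorithm around the progressive
kernel to escape that local optimum. Its defining move is *vertical
decomposition*: cut a candidate alignment into `k` contiguous column
blocks, strip the gaps out of each block, re-align every block from scratch
with the guide-tree method, glue the blocks back together, and keep the
reassembly only if the fitness improved. Decomposition is applied to every
individual of the initial population and to every child in every
generation.

The fitness being maximised is the weighted sum-of-pairs score (WSPM). For
an alignment with rows $A_1,\dots,A_N$ and columns $1,\dots,L$,

$$S \;=\; \sum_{l=1}^{L} S_l, \qquad
  S_l \;=\; \sum_{i<j} W_{ij}\,\mathrm{cost}(A_i[l], A_j[l]),$$

where the pair weight $W_{ij} = w_i w_j$ is the product of CLUSTAL W
sequence weights. Residue pairs are scored with PAM250; a gap–gap pair
costs 0; runs of residue-against-gap positions are charged the affine
penalty

$$G \;=\; g + n\,x,$$

with $g = -10$ (opening) and $x = -0.2$ (per position), the CLUSTAL W
defaults. Concretely, the package scores each unordered row pair on its
*projection*: delete the pair's gap–gap columns, add the substitution score
of every residue–residue column, and charge $G$ once for every maximal gap
run in either projected row. The projection convention settles a point the
affine formula leaves open (whether a gap–gap column interrupts a run: here
it does not), and it makes the independent brute-force oracle in the test
suite unambiguous.

## Distances, trees and weights

Two distance measures feed guide-tree construction:

* the observed **DP distance** of a pair, `mismatch / align_length`, read
  off a global Needleman–Wunsch/Gotoh alignment (residue-versus-gap columns
  count as mismatches, so the value stays in $[0,1]$);
* the **Kimura protein distance** of two aligned rows,
  $-\ln(1 - D - 0.2\,D^2)$ with $D$ the non-identity fraction over
  positions where both rows carry residues. Gap positions are ignored, and
  only exactly matching characters count as matches — ambiguity codes get
  no fractional credit. Beyond $D \approx 0.8541$ the correction is
  undefined; the implementation caps the distance at 10 with a warning so
  that neighbour joining always receives finite input, mirroring common
  distance-correction practice.

Guide trees are built by classical neighbour joining. The method needs a
*rooted* tree (progressive order and CLUSTAL W weights are defined from a
root), and NJ produces an unrooted one, so the final join becomes the root
with the remaining distance split equally. Midpoint rooting would be the
other defensible choice; final-join rooting was picked because it needs no
extra pass and the progressive result depends only on the topology. Ties in
the NJ criterion break towards the smallest node-index pair, and negative
branch-length estimates are clamped to zero, so tree construction is fully
deterministic. CLUSTAL W weights are the path-sharing rule: each edge
contributes its length divided by the number of leaves below it to every
leaf underneath, and the weights are rescaled to mean 1 (a star tree with
zero branch lengths falls back to unit weights).

## The genetic algorithm

**Seeding.** TR1 is the NJ tree of the DP distances; its progressive
alignment is MSA1. The Kimura distances of MSA1 give TR2 and MSA2. The rest
of the population comes from two tree perturbations: *mechanism 1* selects
each leaf with probability 0.5 and joins the pruned selected/unselected
subtrees (both preserving the base tree's branching order) under a new
root; *mechanism 2* exchanges the labels of two random leaves. The
perturbations are spread evenly over the four mechanism-by-tree
combinations, the remainder going to mechanism 2 on TR1. Sequence weights
are computed once from TR1 and frozen, so WSPM values are comparable across
individuals and generations.

**Children.** Per generation of a population of size $P$ (default 100):
$\lfloor P/4 \rfloor$ single-point and $\lfloor P/4 \rfloor$ multiple-point
crossover children, and up to $\lfloor P/2 \rfloor$ mutation children. Both
crossovers pick one parent uniformly from the top half by fitness and one
from the bottom half. The single-point crossover cuts the better parent at
a random interior column and cuts the other parent row-wise so the residue
counts match on each side; the two recombinants are padded back to
rectangles, cleaned of all-gap columns, and the better one survives. The
multiple-point crossover does this twice — at the leading quarter
($\lceil L/4 \rceil$ columns, scored as standalone slices for both parents)
and at the trailing quarter of the remaining right pieces — and swaps the
middle pieces. The mutation draws one individual, rebuilds a tree from its
Kimura distances, and hill-climbs over leaf exchanges, re-aligning after
each swap, until 50 consecutive swaps fail to improve; the result counts as
a child only if it beats the source individual.

**Survival.** Parents and children are pooled, exact duplicates removed,
and the best half (up to the population size) survives; the incumbent best
therefore always survives (elitism), and the per-generation best fitness is
monotone non-decreasing. The run stops after 100 generations (configurable)
without improvement of the best fitness, with a hard cap as a safety net.

Every stochastic choice draws from R's RNG stream seeded from the
configuration (including the mutation search, which runs in compiled code
but consumes the same stream), so runs are reproducible byte for byte.

## Numerical and design choices

* **Gap model read literally.** A run of length $n$ costs $g + nx$ — the
  first position of a run costs $g + x$ — and terminal gaps are charged
  like internal ones; no end-gap discount is applied anywhere.
* **Profile alignment kernel.** Column-against-column scores are the
  unweighted mean of the cross-pair substitution scores, with pairs
  involving an existing gap scoring 0, and a new gap run costs $G$ once per
  run regardless of profile size; the mean (rather than the sum) keeps gap
  penalties on a comparable scale as profiles grow. Once a gap is inserted
  into a profile it is never removed. DP traceback ties prefer the
  diagonal, then the gap in the second profile, then the first, making
  alignments deterministic.
* **Range scoring.** The 25%-column comparisons in the multiple-point
  crossover score the slice as a standalone sub-alignment (all-gap columns
  dropped, gap runs truncated at the slice boundary, openings re-charged on
  each side). Whether such slice scores should carry gap penalties at all
  is genuinely open; the standalone reading is the cheapest consistent one.
* **Vertical division details.** Column blocks are near-equal, the first
  `L mod k` blocks one column wider. Rows that a block reduces to nothing
  are set aside and re-inserted as all-gap rows; blocks re-align with the
  one-stage guide-tree method (DP distances, NJ, progressive). The operator
  keeps the reassembly only on *strict* fitness improvement, so it can
  never lose ground.
* **Duplicate detection** is exact equality of the canonical alignment
  text — the cheapest sound reading of "no duplication".
* **Degenerate inputs.** All-gap columns are removed after every operator;
  a crossover whose tailoring empties a piece falls back to the better
  parent with a warning; a population that deduplicates below its nominal
  size temporarily shrinks (with a warning) rather than padding with
  copies.

## The synthetic family generator

Real benchmark families (the BAliBase style of reference sets) are not
redistributable inside a package, so tests and examples run on simulated
families with known truth. `generate_family()` draws a random ancestor,
evolves it down a random binary tree built by repeated random joins, and on
every edge applies per-site substitutions (default rate 0.1 per edge) and
indel events (default rate 0.02 per site per edge, geometric lengths of
mean 3, insertions and deletions equally likely). Insertion positions are
tracked against a global column registry, so the true alignment of the
leaves is recorded exactly and every row of it gap-strips back to its
descendant sequence. The defaults were chosen once to give what a
practitioner would call a moderately divergent family — roughly 55–80%
pairwise identity with occasional short gaps, the regime where progressive
aligners are good but not perfect and an optimiser has room to help.

What the simulator does *not* emulate: domain shuffling, long terminal
extensions, inverted repeats, strongly non-uniform rate variation across
sites, and compositional bias. Passing tests on simulated families
therefore show that the algorithm optimises its objective and recovers
truth under homogeneous substitution/indel noise — not that it matches
curated-benchmark accuracy on structurally complex families.

## Problem sizes used by the tests and the acceptance script

The shipped checks run the full algorithm at a reduced scale chosen as a
package default: families of 8 sequences of ancestral length 150, a
population of 20, three vertical divisions, and a 20-generation stall rule,
with 20 replicate families in the decomposition-improvement check and 5 in
the acceptance script. These sizes exercise every code path (both
crossovers, mutation, decomposition, deduplication, termination) while a
complete sweep still runs on a laptop; the algorithm itself scales to the
published settings (population 100, 100-generation patience) through
`vdga_config()`.

## Known limitations

* The progressive kernel is a generic profile aligner; the original
  CLUSTAL-style position-specific gap modulation is deliberately not
  implemented, so absolute WSPM values are not comparable to runs of other
  aligners — only relative comparisons within this package are meaningful.
* WSPM is the optimisation target, not truth: on highly divergent families
  the WSPM optimum can drift away from the generating alignment, and the
  accuracy scores (SPS/CS) can degrade even as fitness improves.
* The Kimura correction saturates near 85% observed difference; families
  beyond that are capped and their guide trees carry little signal.
* SPS/CS evaluation accepts a plain integer list of core columns; no
  annotation-file dialect beyond that is parsed.
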