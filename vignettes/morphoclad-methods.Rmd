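---
title: "Methods: maximum parsimony for morphological character matrices"
author: "morphoclad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maximum parsimony for morphological character matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Morphological systematics still rests on discrete character matrices:
a few dozen taxa scored for a few dozen unordered multistate characters,
with `?` for states that could not be observed and `-` for characters
that do not apply to a taxon.  The standard analysis is maximum
parsimony: find the unrooted tree (or trees) minimising the total
number of character-state changes, summarise the equally best trees by
a strict consensus, quantify homoplasy with consistency and retention
indices, attach nonparametric bootstrap percentages, and map the
unambiguous synapomorphies onto the consensus.  `morphoclad`
implements that entire workflow, and ships the 33-taxon x 67-character
matrix of the darkling-beetle tribe Helopini (Tenebrionidae) as a
fully worked fixture: on that matrix the packaged defaults reproduce
the analysis summary (12 most parsimonious trees of 301 steps; strict
consensus of length 314) that the matrix is known for.

## Optimization model

Characters are unordered (Fitch): a change between any two states
costs one step.  On binary trees the engine runs the classic two-set
Fitch pass; on multifurcating trees (consensus trees, collapsed trees)
it runs the Hartigan generalisation, which at each vertex keeps the
states attaining the maximum count over the child state sets and adds
`(number of children - count)` steps.  The two agree wherever both
apply, and both equal a uniform-cost Sankoff dynamic program, which
the test suite uses as an independent oracle (alongside an
independently developed Fitch implementation from another package).

Missing (`?`) and inapplicable (`-`) cells are *optimization-neutral*:
the cell is treated as the full set of states observed in its column.
This is the convention of the classic cladistics programs; reported
tree lengths depend on it, so no special inapplicable machinery is
attempted.  Length is invariant under re-rooting, so trees are stored
unrooted and rooting (on the designated outgroup) is purely a display
operation.

Per-character step bounds are the standard quantities: `m`, the number
of observed states minus one (minimum conceivable steps on any tree),
and `g`, the number of scored taxa minus the frequency of the
commonest state (steps on the completely unresolved star tree).  From
observed steps `s` the indices are `ci = m/s` and `ri = (g-s)/(g-m)`;
ensembles use the sums, `CI = M/S`, `RI = (G-S)/(G-M)`.

Two reporting conventions differ between programs: whether
parsimony-uninformative characters enter the ensemble sums.
`index_report()` computes both (`all` and `informative`); on the
packaged fixture every character is parsimony-informative, so the two
coincide there, and `all` is the reference convention.  Display of
index values follows the original programs, which **truncate** (not
round) to two decimals; `0.2957` prints as `0.29`.  Full precision is
retained in the report objects.

## Heuristic search

`heuristic_search()` reproduces the classic NONA-style strategy:

1. *Random-addition Wagner trees.*  Each replicate draws a random
   taxon addition order from a seeded stream (replicate *i* uses the
   *i*-th draw, so runs are replayable bit-for-bit) and inserts taxa
   greedily at the length-minimising branch, ties broken by a
   deterministic traversal order.
2. *TBR swapping.*  All bisections x reconnection pairs are evaluated
   through directed Fitch state sets (two passes per bisected
   component, then O(characters) per reconnection), first improvement
   restarts the sweep, and equal-length distinct topologies are held
   up to `hold` (default 20) and swapped in turn until closure.
3. *Final sweep.*  Best trees pooled over replicates are TBR-swapped
   to completion, FIFO order, capped at `max_trees` (default 10,000);
   hitting the cap is flagged.
4. *Collapsing.*  Branches whose minimum length over all
   most-parsimonious reconstructions is zero - no character change is
   forced on them - are collapsed (the "ambiguous" rule, selectable via
   `collapse`), and topological duplicates are removed by comparing
   bipartition sets.

The defaults (`n_replicates = 1000, hold = 20, max_trees = 10000`)
are the classic protocol for matrices of this size; on the packaged
fixture the same best length and tree set are reached from ~10
replicates, which is what most tests use.  The per-branch forced /
ambiguous classification is exact: it comes from a uniform-cost
dynamic program over all rootings (per-state subtree costs in both
directions of every branch), not from comparing accelerated and
delayed transformations, and is cross-checked against brute-force
enumeration of all most-parsimonious labelings in the tests.

Two readings of the ambiguous-collapse rule exist in the literature
(collapse when *some* reconstruction puts zero changes on the branch
versus when *all* do).  The implemented rule is the first; on the
fixture it yields exactly 12 distinct collapsed trees, consistent with
the analysis the matrix comes from, so the alternative was not needed
(collapsing can be disabled with `collapse = "none"`).

`exhaustive_search()` enumerates all `(2n-5)!!` topologies (refusing
more than 10 taxa) and is the oracle for every search property test.

## Consensus and bootstrap

`strict_consensus()` keeps exactly the bipartitions common to all
input trees, built by nesting the shared splits; `majority_consensus()`
keeps splits above a cutoff (>= 50%, compatible by pigeonhole).  The
consensus length reported everywhere is the polytomy-general (Hartigan)
length of the consensus topology itself.  How the original programs
scored a polytomous consensus is not documented; Hartigan-style
optimization is the natural reading and reproduces the fixture's
published consensus length, so the best-binary-resolution alternative
was not implemented.

`bootstrap_support()` resamples characters with replacement, carrying
the multiplicities as integer column weights rather than materialised
duplicate columns (identical lengths, faster).  Each replicate runs a
reduced heuristic search and votes **once per bipartition of the
replicate's strict consensus** (`vote = "consensus"`), which prevents a
replicate with many ties from over-voting; per-tree averaged voting is
available (`vote = "per_tree"`) since published protocols are often
ambiguous on this point.  Frequencies are percentages of effective
replicates; failed replicates are dropped and the denominator
adjusted.

The inner-search effort matters in a specific, documented way: with a
*single* random-addition replicate per resample the replicate trees
are biased toward the addition order, replicates become spuriously
similar, and apparent support is inflated (we observed weakly
supported splits gaining 5-15 points under `inner_replicates = 1`).
The default (`inner_replicates = 3, hold = 10, max_trees = 50`) is the
point where support values stabilise on matrices of the fixture's
size; the classic full protocol (100 inner replicates, hold 20, cap
1000) gives the same counts at ~30x the cost.  On the fixture, seven
consensus branches exceed 50% at 1000 replicates - the six strongly
supported ingroup groupings plus the outgroup pairing - one more than
the published count, which is within one clade of it; values near the
50% line move by a few points across seeds (binomial error at 1000
replicates is about +/-1.6 points at 50%).

## Character-removal sensitivity analysis

`removal_analysis()` is a leave-one-out loop ("sequential" in the
sense of iterating over characters, not cumulative deletion - each
reduced matrix lacks exactly one character): re-search, rebuild the
strict consensus, and compare its polytomy-general length, resolved
split count and tree count against the full-matrix baseline.  A
character is flagged when the consensus length *drops* by more than
`threshold` steps (default 30).  A drop that large exceeds any single
character's own step contribution; it can only arise from a topology
shift - the consensus collapsing or re-resolving once the conflicting
signal is gone - which is precisely what makes the flagged character
"conflict-inducing".  Sub-searches default to 20 replicates each;
full-protocol effort is a parameter away but rarely changes the flags.

## Synapomorphy mapping

`common_synapomorphies()` maps a transformation (character, derived
state) onto a consensus branch only when it is unambiguous there -
every most-parsimonious reconstruction changes on that branch to the
same derived state - *and* the same transformation is unambiguous on
the matching branch (same bipartition) of every MPT.  Branch matching
across trees uses bipartitions, so MPT branches absent from the
consensus contribute nothing; characters whose unambiguous changes
never agree on a common branch are listed separately as orphans.
"TNT-style common synapomorphies" is not formally specified anywhere;
this intersect-across-trees reading is the implemented one, and on the
fixture it recovers exactly the seven unique (ci = ri = 1)
synapomorphies the matrix is known for.  A transformation is *unique*
when the character's consensus steps equal its minimum `m` (with
`m > 0`), i.e. ci = ri = 1; all others are homoplasious.

## Synthetic data

`simulate_matrix()` places an explicit Poisson(`change_rate`) number
of changes per character on uniformly drawn branches (new state
uniform among the other states), rather than simulating a
continuous-time Mk process.  The trade-off is deliberate: explicit
placement gives exact truth bookkeeping (which branch, which states)
and direct control of homoplasy, which the oracle tests need more than
they need model realism.  Consequences to keep in mind: change counts
do not depend on branch lengths (there are none), characters are
independent and rate-homogeneous, and masking to `?`/`-` is random
rather than logically structured - in real matrices inapplicable
states cluster by controlling characters, but the engine treats `-`
as missing, so random masking exercises the same code path.  Passing
recovery tests on these data therefore demonstrates correctness of
the inference machinery, not robustness to correlated characters or
structured missingness.

Defaults mirror the packaged fixture's scale: 33 taxa, 67 characters,
up to 4 states per character, ~1% missing and ~3% inapplicable cells
(the fixture's observed rates are 0.9% and 3.3%); `change_rate = 2`
puts realized ensemble CI in the fixture's neighbourhood.
`two_signal_matrix()` builds a clean majority signal plus a
contradictory minority block for the sensitivity tests.
`random_tree()` is uniform over unrooted binary topologies via
sequential addition.  All generators are seed-deterministic.

## Numerical and engineering choices

* State sets are bitmasks (states 0-9); split identities are 64-bit
  leaf bitsets, so trees are limited to 64 leaves in the search
  engine.
* All tie-breaks (Wagner insertion, TBR neighbour order, FIFO final
  sweep) are deterministic; the only randomness is the seeded R stream
  that draws addition orders, bootstrap weights and simulations.
  Derived seeds stay below 2^31.
* Tree identity = equality of informative bipartition sets, never
  newick string comparison; `canonical_newick()` exists for tests and
  reporting.
* Degenerate inputs: an all-missing column contributes 0 steps and
  `m = g = 0` (its per-character `ci` is reported as undefined rather
  than 1 to avoid inflating summaries); ensemble `CI` is undefined
  when `S = 0`, `RI` when `G = M`.
* Test problem sizes: property tests exhaust all 105 six-leaf and 945
  seven-leaf topologies; oracle comparisons use 5-9 taxa where
  enumeration is exact; fixture searches in the suite use 12-100
  replicates, which reach the same tree set as the full 1000-replicate
  protocol on this matrix.

## Known limitations

Ordered/additive characters, step matrices, polymorphic cells
(`[01]`), implied weighting and Bremer support are out of scope, as
are likelihood/Bayesian scoring and "new technology" searches
(ratchet, sectorial, fusing).  Inapplicable states are not modelled
beyond the missing-data convention.  The bootstrap clade count near
the 50% threshold is seed-sensitive by one clade on the fixture, as
discussed above.
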