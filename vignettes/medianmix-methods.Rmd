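---
title: "Inferring ancestral gene orders with medianmix: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring ancestral gene orders with medianmix: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Given the gene orders of present-day genomes and the phylogeny relating
them, what were the gene orders of their ancestors? `medianmix` answers
this for circular unichromosomal genomes evolving by inversions — the
setting of organellar and many bacterial genomes — when all genomes share
one set of `n` genes.

Two established strategies trade accuracy against time. *Direct
optimization* repeatedly solves the NP-hard median problem (find the
genome minimizing the summed rearrangement distance to three neighbours)
until the whole tree's event count stops dropping; it is accurate but can
be intractable once genomes are distant. *Likelihood reconstruction*
computes, for every candidate gene adjacency at an ancestral node, a
posterior probability from the leaves, then assembles a genome from the
most probable adjacencies; it is fast but less accurate. `medianmix`
implements both, plus the hybrid that is its point: use the likelihood
stage to propose adjacencies, use randomized constrained medians to find
out *which* of those proposals the parsimony criterion keeps endorsing,
and fix the endorsed ones in a final, much smaller, median search.

## Genomes as perfect matchings

Gene `i` has two extremities, tail `2i-1` and head `2i`. Reading `+i`
enters at the tail; `-i` at the head. Each neighbouring gene pair in the
circular order contributes an edge between the facing extremities, so a
genome is exactly a perfect matching on `1..2n` (its breakpoint-graph
edge set), and

```{r}
adjacencies_of(genome(c(1, 4, 2, -3, 5)))
```

returns the five edges (10,1), (2,7), (3,8), (4,6), (5,9). The DCJ
(double-cut-and-join) distance between genomes `a` and `b` is `n - c`
with `c` the number of alternating cycles in the union of their
matchings; one inversion is one DCJ step. We use this cycle distance
throughout — including inside the median solver, whose machinery (cycle
counting, adequate subgraphs, edge surgery) is defined on cycle
structure. A genome equals any rotation of itself and its
reverse-complement reading; the canonical form (gene 1 first, forward)
makes equality and accuracy counting unambiguous.

## The median solver

`solve_median()` maximizes, over perfect matchings `M` on the shared
vertex set, the total cycle count of `M` against the three input
matchings (equivalently it minimizes the median score `3n - cycles`).
Search choices, in the order they matter:

* **Single-circle constraint.** The median must be one circular
  chromosome. A path structure (`oend[x]` = opposite end of the partial
  genome path containing extremity `x`) rejects any edge closing a circle
  before all genes are linked; the final edge is exempt. This also rules
  out joining the two extremities of one gene.
* **Bound.** At a node with `rem` median edges still to choose, at most
  one new cycle per genome per future edge is attainable, so
  `cycles + 3*rem` bounds the total. The bound is admissible — it never
  underestimates — hence no optimum is pruned; the test suite checks this
  against exhaustive enumeration on hundreds of random five-gene triples.
* **Adequate pairs.** A vertex pair joined by two or more parallel genome
  edges is an adequate subgraph of the smallest size: committing it
  closes at least 2 of at most 3 attainable cycles. Such pairs are
  committed eagerly, without branching, cascading as the rewiring creates
  new parallel pairs (`adequate = "pairs"`; `"triples"` and `"off"`
  restrict or disable this). Eager commitment is what makes low-rate
  medians of 100-gene genomes finish in milliseconds.
* **Adjacency fixing.** A constraint adjacency `(i,j)` is forced in by
  edge surgery: any matching lacking it has its edges `(i,a)`, `(j,b)`
  replaced by `(i,j)`, `(a,b)`. All three genome edges at `i`,`j` are then
  parallel, so the pair is adequate and the pair of vertices leaves the
  search. The reported score is always recomputed against the *original*
  genomes (the surgery inflates the internal cycle count by exactly one
  per rewired matching, a constant offset that cannot change the argmin).
* **Branching order and ties.** The lowest free vertex is matched against
  candidates ordered by parallel-edge multiplicity, then input-genome
  order, then vertex id; among visited equal-score optima the canonically
  smallest genome is kept. Many triples have several optimal medians
  (the three-gene worked example already does), so a deterministic tie
  policy is what makes every downstream result reproducible bit for bit.
* **Budget.** `budget` caps branch-and-bound nodes (default `1e7`,
  roughly seconds); on exhaustion the best complete median found so far
  is returned flagged `optimal = FALSE`. A first greedy descent seeds the
  incumbent so a valid genome always exists.

Degenerate rewiring cases (a matching already containing the committed
edge) credit a cycle instead; the `a = b` self-loop case cannot arise
between two perfect matchings.

## The likelihood stage

`adjacency_posteriors()` treats each candidate adjacency as a two-state
(present/absent) character. One inversion breaks 2 of the `n` adjacencies
of a circular genome, giving per-event loss `2/n`; the matching gain for
one specific absent adjacency is `(2/n)/(2n-3)` (a freed extremity picks
its partner uniformly among the `2n-3` legal ones). Closing the chain
over a branch with `t` expected events (real-valued `t`):

* P(present stays present) `= pi + (1 - pi) * g^t`
* P(absent becomes present) `= pi * (1 - g^t)`

with `g = 1 - 2/n - (2/n)/(2n-3)` and stationary prior
`pi = 1/(2n-2)`. The closure — rather than a bare survival power — is
what gives both limits the model must honour: at `t = 0` the transition
is the identity, and as `t` grows every posterior relaxes to the prior.
Branch lengths of `1e-8` events floor the zero-length case so conflicting
leaves under a zero-length branch resolve by majority weight instead of
0/0. Candidate adjacencies are those observed in at least one leaf;
everything else sits at the prior. Adjacencies are treated independently
in the recursion (the standard pruning approximation); their dependence —
each extremity has exactly one partner — enters at assembly.

`assemble_ml_genome()` is a greedy maximum-weight matching under the same
single-circle path rule as the median solver: candidates by decreasing
posterior, ties by vertex id; premature circle closures are skipped.
When the observed candidates run out, the remaining adjacencies all carry
the prior, so the greedy rule reduces to joining the remaining path ends
lowest-id-first; this completion is part of the algorithm, not an error
path.

Branch lengths: when true per-branch event counts are known (simulation
benchmarks) they are used; otherwise `estimate_edge_lengths()` fits
nonnegative lengths to the pairwise leaf DCJ distances by least squares.
Feeding the truth makes the likelihood stage somewhat stronger at high
divergence than a reconstruction that must estimate lengths — visible as
a few accuracy points at the largest benchmark diameters.

## The mixture stage

Only part of the likelihood genome's adjacencies are correct, and apart
from a small high-posterior fraction their posteriors are too similar to
tell which. `rank_adjacencies()` answers statistically: in each of `R`
replicates (default 100, where the ranking empirically reaches a steady
state), fix the high-posterior adjacencies (posterior above 0.90) plus a
uniform random sample of the rest — `round(0.72 * n)` in total, the
midpoint of the effective 70–75% band; should the threshold alone
over-select, the highest-posterior quota is kept — and solve the
constrained median of the node's three neighbours. Every likelihood
adjacency *not* fixed in a replicate is eligible; its count increments
when the median output contains it anyway. Normalizing counts by
eligibility (rather than by `R`) avoids penalizing adjacencies that were
often fixed. Randomly fixed sets are always mutually compatible because
they are drawn from one genome's adjacency set.

`select_and_finalize()` ranks by occurrence rate (ties: posterior, then
vertex id; never-eligible high-posterior adjacencies rank at rate 1),
fixes the top `selection_percentage * n`, and solves one final
constrained median. The selection percentage defaults to 0.70 when
genomes are closely related (per-edge rate at most 24% of `n`, or tree
diameter at most 3) and 0.75 otherwise, the two-level rule the benchmark
tables support; values outside the tested 0.65–0.85 band warn.

`refine_tree()` composes this over the tree: initialize every internal
node with its likelihood genome, then sweep, re-deriving each node from
its three current neighbours and accepting an update when its local
median score does not increase — which makes the tree score (summed DCJ
distance over branches) non-increasing, so stopping at the first sweep
with no strict decrease terminates. Ranking is re-run each sweep by
default (`rank_once = TRUE` ranks only in the first sweep); the
per-replicate medians are independent and could run in parallel, but the
sequential order is kept so one seed fixes the entire output.

## The simulator and what it does (not) emulate

`simulate_dataset()` draws a uniform random unrooted binary topology by
sequential edge subdivision, assigns each branch an expected event count
— uniform in `rate*n*(1 ± fluctuation)` (defaults 0.12 and 0.5), or, in
the diameter-controlled model, exponential weights rescaled so the
longest leaf-to-leaf expected-event path equals `diameter*n`, which
yields the unbalanced branch lengths regarded as more realistic — places
the identity genome at an internal root (accuracy is invariant to this
relabeling), and applies `round(length)` inversions with uniform
endpoints along each branch. Defaults `n = 100` genes and 10 leaves are
the community's standard benchmark scale; the gene count is a first-class
configuration field so every experiment records it. The simulator shares
the inference model's event type (inversions on one circular chromosome)
but none of its code; it does not emulate transpositions, unequal gene
content, duplications, or multichromosomal events, so benchmark accuracy
says nothing about those regimes.

`adjacency_accuracy()` is the fraction of inferred adjacencies present in
the true ancestor; experiment means average it over all internal nodes of
all datasets, unweighted. `run_experiment()` derives one seed per dataset
and one per inference from its base seed, making reports bit-reproducible.

## Numerical and design choices, in brief

* Integer tree scores plus accept-on-no-increase guarantee refinement
  terminates; `max_sweeps = 20` is a safety net (typical runs converge in
  2–4 sweeps).
* Benchmark problem sizes used by the shipped acceptance script: 100
  genes, 10 leaves, 10 datasets for likelihood-only numbers, 5 for the
  pure-median number; at these sizes the whole script runs in well under
  a minute.
* The node budget defaults to `1e6` per median call inside the mixture
  (`1e7` for standalone `solve_median()`); budget-exhausted replicates
  are kept and counted in the occurrence table's `budget_exhausted`
  attribute.
* Known limitations: very distant genomes (per-edge rates beyond ~40% of
  `n`) leave the likelihood stage with too few correct adjacencies for
  the mixture to screen, and accuracy degrades for every method;
  topology inference is out of scope (the phylogeny is an input).
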