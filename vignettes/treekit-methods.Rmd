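---
title: "treekit: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{treekit: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treekit)
```

## The data model

`treekit` deliberately keeps its data model to two classes. A `tree_node`
carries a label, an optional branch length to its parent, a parent
reference, an ordered list of children, and a free-form attribute list; a
`treekit_tree` is a root plus a rootedness flag and is the handle for
traversal and manipulation. Everything else in the package — parsers,
statistics, the LTT machinery — is a function over these two types. The
point of the minimalism is scale: no per-node bipartition records, hash
registries, or taxon namespaces are maintained, because those structures
pay off only when comparing many trees over a shared taxon set, which is
outside this package's scope. The cost of that choice is that multi-tree
comparison metrics (Robinson–Foulds and friends) are not offered.

Nodes are R environments, so they have reference semantics: `add_child()`,
`detach_node()`, `reroot()` and `prune_leaves()` mutate in place, and two
variables can point at the same node. This is the natural fit for a
linked structure in R — copy-on-modify lists would copy entire subtrees on
every edit. Benchmarked on this design, 200,000 nodes build in about two
seconds and occupy ~12 MB, which is what makes the 10^5–10^6-leaf regime
practical in pure R.

Two conventions are load-bearing and worth stating once:

* **Missing branch lengths are not zero.** A node whose length was absent
  in the input round-trips as absent. In *path arithmetic* (height,
  patristic distances, root-distance order, gamma, LTT) a missing length
  counts 0, because those sums must be total; in `avg_branch_length()`
  missing lengths are *excluded*, because an absent measurement is not
  evidence of a zero-length branch.
* **Children are ordered** and every operation preserves insertion order.
  Traversals and serialization are therefore deterministic, which the test
  suite relies on throughout.

Tree equality for testing is label-preserving isomorphism with edge lengths
compared at 10^-9 relative tolerance (`trees_isomorphic()`): child order is
ignored, absent lengths only match absent lengths. It is an explicit
comparison, never object identity.

Node labels are not required to be unique; uniqueness is enforced only
among leaves and only by the operations that use labels as keys (`mrca()`,
`distance_matrix()`, `extract_tree_with()`, `prune_leaves()`), which raise
a lookup error on ambiguity rather than guessing.

## Parsing and writing

The Newick parser is single-pass over a token stream: one vectorized
`gregexpr()` call finds all structural characters (`( ) , : ;`), one
`substring()` call lifts the text between them, and a single R loop of
O(#tokens) — not O(#characters) — builds the nodes. Quoted labels and
square-bracket comments are masked out beforehand so the structural scan
cannot be confused by a `(` inside a label; inputs without quotes or
comments (the overwhelmingly common case for machine-written large trees)
skip masking entirely. Parse errors report a character offset. A 100,000-
leaf tree (~3.5 MB of Newick) parses in roughly two seconds.

Dialect decisions, made once and kept:

* Underscores in unquoted labels are preserved verbatim, never turned into
  spaces; the space convention is ambiguous across tools and breaks
  round-tripping.
* Comments are retained verbatim in the attribute list of the node whose
  syntactic position they follow (keys `comment1`, `comment2`, ...), except
  a leading `[&R]`/`[&U]`, which sets the rootedness flag. Comments are
  never parsed as structure.
* `read_tree_newick()` on multi-statement input returns the first tree;
  `read_trees_newick()` returns all of them. The singular reader is the
  common case; silently concatenating trees would be a trap.
* Numbers serialize with the shortest of 15 or 17 significant digits that
  round-trips the stored double, unless an explicit `precision` is given.
  This makes serialization byte-stable, which the generator's determinism
  contract depends on.

Files are sniffed for the gzip magic bytes `1f 8b` — extension is ignored —
and decompressed transparently; a literal string, a plain file and a gzip
file with the same content produce isomorphic trees. NEXUS support covers
the TREES block (named trees, `TRANSLATE` substitution applied to leaf
labels, `[&R]`/`[&U]` hints, quoted names); NeXML support covers the
structural subset (nodes, edges, labels/otu references, lengths), with
other node attributes retained opaquely. Neither NEXUS nor NeXML *writing*
is offered: Newick is the output format, and the test suite uses a small
test-only NeXML emitter for round-trip checks.

## Traversal

Five orders are provided — pre-, in-, post-, level- and root-distance
order, plus a leaves-only convenience. All are iterative with explicit
stacks or queues; R's recursion limit is never a constraint, which the
suite demonstrates on a caterpillar with 10^5 internal nodes. The
`traverse_*()` functions return lazy iterators (`next_node()` /
`as.list()`): pre-order, post-order, level-order and leaves advance one
step per call, so taking the first k nodes of a huge tree does work
bounded by the visited frontier. In-order and root-distance order must
examine structure globally (topology check, depth sort) and therefore
precompute; their iterators exist for interface uniformity.

Semantics that the underlying definitions leave open were fixed as
follows:

* **In-order on a non-binary node is an error** (an
  unsupported-topology condition naming the node), not an arbitrary split
  of the children. A silent convention here would quietly change results
  between tools. Unary chains are permitted, visiting child before node.
* **Root-distance order uses weighted distance** (sum of branch lengths,
  missing as 0), matching the patristic metric used everywhere else, not
  edge counts. Ties — including the all-lengths-missing degenerate case —
  break by pre-order discovery rank, making the order total and stable.

## Manipulation

`reroot()` reverses the edges on the path from the new root to the old
one, each keeping its length, and moves any stored root edge to the new
root, so total branch length is conserved exactly (not merely to
tolerance) and leaf-to-leaf patristic distances are invariant. Two
rooting behaviors exist in the wild, so both are explicit: rerooting *at a
node* makes that node the root (its former parent becomes a child);
passing `length_along_edge` bisects the node's parent edge and roots at
the split point. An old root left unifurcating is suppressed automatically
— otherwise repeated rerooting accumulates degree-2 junk nodes.

`extract_tree_with()` copies (read-style usage: take a subproblem without
risking the original), `prune_leaves()` edits in place (write-style usage);
they are complements on the leaf set, and both finish with unifurcation
suppression, summing lengths along collapsed paths so distances among the
surviving leaves are exactly preserved.

## Statistics

`distance_matrix()` runs one post-order pass that carries, for each node,
the indices of and distances to the leaves below it, joining child groups
with a vectorized outer sum; the cost is the unavoidable O(n^2) of the
output plus one traversal, never one MRCA query per pair. `mrca()` resolves
a label set by folding pairwise ancestor climbs with temporary marks,
O(k·depth) per query. A precomputed ancestor table (binary lifting) was
considered and rejected: with no all-pairs-MRCA operation in the interface,
climbing meets every tested workload, and the table would add per-tree
state that must be invalidated on every structural edit.

`treeness()` counts a stored root edge as internal — it is not a terminal
branch — a point worth stating because published definitions vary.

`gamma_statistic()` derives the internode intervals g_2..g_n from the
sorted branching-event depths (for n leaves there are exactly n-1 events)
and evaluates

$$\gamma = \frac{\frac{1}{n-2}\sum_{i=2}^{n-1}\sum_{k=2}^{i} k\,g_k - T/2}
{T\sqrt{1/(12(n-2))}}, \qquad T = \sum_{j=2}^{n} j\,g_j .$$

Numerical choices: leaf depths are accepted as ultrametric when the
maximum deviation is at most 10^-6 of the height (floating-point depth
sums drift, and a hard equality test would reject legitimate ultrametric
input); a node with c > 2 children contributes c-1 coincident branching
events with zero-length intervals, the continuous limit of the binary
definition. The implementation is vectorized (`cumsum`); the test suite
checks it at 10^-9 against a deliberately naive double-loop oracle and
against `ape::gammaStat`.

`min_leaf_distances()` is the canonical post-order fold: 0 at leaves,
minimum of child value plus child edge at internal nodes; the root's entry
is the minimum root-to-leaf distance.

## Lineages-Through-Time

`ltt()` computes the step function of lineage count against time. Time
runs *forward from the root at 0* — the convention that remains
well-defined for non-ultrametric trees, where "time before present" is
not; users of backward-time axes can negate. A branching node with c
children raises the count by c-1 at its depth; a leaf ending strictly
before the last tip lowers it by 1. Simultaneous events merge into one
point with the net change, keeping times strictly increasing. A stored
root edge shifts the origin, with the single root lineage occupying
[0, root edge); this makes the integral of the step function equal the
total branch length on every tree, a conservation law the tests assert at
10^-9. The leaf-death comparison uses a 10^-12 relative tolerance so that
float jitter among separately-summed ultrametric tip depths is not
misread as early extinction. Computation and rendering are separated:
`ltt()` returns a plain data frame (testable without any graphics), and
`plot_ltt()` is a thin ggplot2 adapter — log-scaling is applied by the
axis, never by transforming the data.

## The random-tree generator

`generate_tree()` exists so that every algorithm in the package can be
exercised on realistic, reproducible inputs of any size without shipping
data. Three models, chosen to cover the code paths that matter:

* **yule** — forward-time pure birth at rate `rate` (default 1): with k
  lineages the next split arrives after Exp(k·rate) and hits a uniformly
  chosen lineage. The tree is observed one further Exp(n·rate) waiting
  time after the n-th tip appears. That observation window matters: it
  makes every internode interval g_k an independent Exp(k·rate) draw,
  which is the regime in which the gamma statistic has its ~N(0,1)
  pure-birth null; stopping exactly at the n-th split would force
  g_n = 0 and bias gamma negative. Ultrametric.
* **coalescent** — Kingman-style pairwise merging backward in time with
  Exp(rate·k(k-1)/2) waits. Ultrametric, with the deep-branch geometry
  (gamma strongly positive) that stresses the LTT and gamma paths from
  the opposite side.
* **random_attachment** — each new leaf attaches at a uniform point on a
  uniformly chosen existing edge, with pendant lengths drawn from an
  exponential, uniform or constant law. Non-ultrametric, exercising the
  general-metric paths (leaf deaths in LTT, min-leaf distances below the
  height).

Trees are built as flat parent/length vectors and materialized in one
pass; identical parameters and seed give byte-identical Newick, and the
caller's random stream is saved and restored. Defaults (rate 1, unit
exponential lengths) are conventional simulation settings; sizes are
always explicit.

What the generator does *not* emulate — and therefore what passing tests
do not certify about real data: polytomies and zero-length branches from
unresolved inference, support values stored as internal labels, duplicate
or messy taxon names, rate variation across lineages, and sampling
fractions. The parsers and statistics handle several of these (polytomies,
internal labels, quoted names) and are tested on them separately with
hand-built inputs, but the bulk random sweeps are clean binary trees.

## Problem sizes and tolerances in the checks

The shipped suite verifies, among others: round trips on 200 random trees
of 2–512 leaves across all three models (lengths at 10^-9); traversal
contracts exhaustively on all 85 rooted tree shapes with at most 7 nodes
plus 100 random trees; distance-matrix and MRCA agreement with brute-force
oracles on 50 trees of up to 64 leaves (exact, not toleranced — the two
computations sum the same numbers in the same order); conservation laws on
30 random trees; gamma against a direct-formula oracle on 100 ultrametric
trees at 10^-9 and its pure-birth null moments over 2000 Yule trees with 50
leaves (mean within ±0.1, variance within [0.8, 1.2]); and a full
generate → serialize → re-parse → post-order cycle at 100,000 leaves.
These sizes were chosen to finish comfortably on a single CPU while leaving
the asymptotic claims visible; the same measurements are recomputed
end-to-end by `scripts/acceptance.R`.

## Known limitations

* `distance_matrix()` allocates the full n × n double matrix: ~800 MB at
  n = 10^4 ... 10^4.5; beyond that, compute distances per pair or extract
  subtrees first.
* The NEXUS reader covers the TREES block as used by the major tree
  producers; exotic constructs elsewhere in a document are ignored rather
  than validated.
* Rooting policies that *choose* a root by an optimality criterion
  (midpoint, outgroup objective functions) are not included; `reroot()` is
  the mechanism, not the policy.
* Error offsets in Newick refer to the comment/quote-masked text when such
  constructs are present, so they can be shifted slightly on heavily
  annotated inputs.
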