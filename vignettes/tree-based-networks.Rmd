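---
title: "Tree-based unrooted phylogenetic networks: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree-based unrooted phylogenetic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbnet)
```

## The model

An *unrooted binary phylogenetic network* on a taxon set $X$ is a connected,
simple graph in which every vertex has degree 1 or 3 and whose degree-1
vertices are exactly the taxa.  Networks generalize unrooted binary
phylogenetic trees and are used to represent non-tree-like evolution —
horizontal gene transfer in bacteria, hybridization in plants — or
uncertainty about a tree.  A natural way to build such a network, used by
reticulogram software, is to start from a phylogenetic tree and add edges
between points on its branches.  The networks obtainable this way are
exactly the *tree-based* networks: those containing a *support tree*, a
spanning tree whose leaves are exactly $X$.  Suppressing the degree-2
vertices of a support tree yields a *base-tree* on $X$ — the tree signal
that the network "is based on".

Not every network is tree-based, and `tbnet` exists to make the structure
of the tree-based ones computable:

* **Decomposition.** Cut-edges (bridges) split the taxa; a network is
  *proper* when every cut-edge does so on both sides.  The 2-edge-connected
  pieces with more than one vertex are the *blobs*; each blob $B$ together
  with its incident cut-edges forms a *simple* network $B_N$ (all cut-edges
  trivial).  A network is tree-based **iff** every $B_N$ is, because every
  cut-edge belongs to every support tree.  This is `blobs()`,
  `blob_network()`, `is_proper()`, and the decomposition used inside
  `find_support_tree()`.
* **Level.**  A network has *level* $k$ (at-most semantics) when each blob
  becomes a tree after deleting at most $k$ edges; the *strict level* is
  the maximal blob cycle rank $|E(B)| - |V(B)| + 1$.  Every **proper
  network of level at most 4 is tree-based**, and 5 is the minimal level
  where that fails.  `strict_level()` / `is_level()` expose both readings,
  matching the usage "level-$k$" vs "strictly level-$k$".
* **Hardness.**  Deciding tree-basedness is NP-complete, by reduction from
  Hamiltonicity of cubic graphs: subdividing an edge $e$ of a cubic graph
  $C$ twice and hanging leaves $x, y$ gives the network $C_e(x,y)$, and
  $C$ is Hamiltonian iff some $C_e(x,y)$ is tree-based iff some support
  tree is an $x$–$y$ path.  The Petersen graph, famously non-Hamiltonian,
  yields a simple strictly level-6 network on two taxa that is not
  tree-based (`cubic_to_network(petersen())`).
* **Rooted correspondence.**  A network is tree-based iff, for any leaf
  $x$, its edges can be oriented so that removing $x$ leaves a rooted
  tree-based binary network (root = the former neighbour of $x$).
  `orient_from_support_tree()` implements the constructive direction;
  `attach_leaf_at_root()` is its exact inverse.
* **Fully tree-based = level 1.**  A network in which *every* subtree with
  leaf set $X$ spans (is a support tree) is called fully tree-based; this
  holds exactly for level-1 networks.  `is_fully_tree_based()` returns the
  characterization, `fully_tree_based_direct()` verifies the definition by
  exhaustive subtree search — keeping the equivalence a *tested* property
  rather than an assumption.

## Exact recognition

`find_support_tree()` answers the NP-complete question exactly.  The
search is depth-first edge-inclusion backtracking over the non-bridge
edges of one simple network at a time:

* all cut-edges are forced into the tree (they are in every spanning
  tree, and pendant edges pin the taxa at degree 1);
* a union–find structure rejects any inclusion that closes a cycle;
* a branch dies as soon as an internal vertex can no longer reach degree
  2 (spanning mode) or is stranded at degree 1 (subtree mode) — support
  trees may bend through internal vertices but never terminate at them;
* blobs are solved independently and the per-blob trees spliced with the
  cut-edges, so the exponential worst case is confined to single blobs.

Edges are considered in lexicographic order with the inclusion branch
first, so witnesses and enumeration order (`enumerate_support_trees()`)
are deterministic.  All searches accept a node-expansion `budget`;
exhausting it raises a distinct `tbnet_budget_error` ("undecided"), never
a false "no".  The same engine, in subtree mode, powers `displays()`
(displayed trees need not span) and the definitional fully-tree-based
verifier; `is_based_on()` filters enumerated support trees by leaf-fixed
isomorphism of their base-trees, via colored VF2.

`is_tree_based()` optionally short-circuits with the structural facts
(single-taxon case; not proper ⇒ not tree-based; proper and strict level
≤ 4 ⇒ tree-based).  The test-suite and the acceptance script always use
`use_shortcuts = FALSE` or `find_support_tree()` where those facts are
themselves under test, so their verification rests on search alone.

Rooted tree-basedness (`is_rooted_tree_based()`) is solved exactly by
branching over the per-reticulation choice of retained incoming arc
($2^r$ assignments): in a DAG, one retained in-arc per non-root vertex is
automatically a spanning arborescence, so the only side condition is that
no internal vertex is left without an outgoing arc.  This is exponential
only in the reticulation count, which is small at desk scale; we use it
instead of the known polynomial-time algorithm for the rooted problem to
keep the package self-contained and exhaustively checkable.

## Generators and enumerators

**Cubic multigraph generators.**  Every simple level-$k$ network arises by
inserting pendant leaf edges into a connected cubic multigraph on
$2k - 2$ vertices (loops allowed, counting 2 toward the degree).
`enumerate_cubic_multigraphs(n)` enumerates these generators up to
isomorphism with a compiled backtracking enumeration over multiplicity
matrices; class representatives are deduplicated by hashed
colour-refinement invariants plus exact backtracking isomorphism (hash
collisions can only weaken the colour constraint — membership is always
confirmed exactly).  The class counts produced (2, 5, 17, 71 for
$n = 2, 4, 6, 8$) are cross-checked in the tests against an independent
labelled enumeration with permutation-based canonical forms at small $n$.
`networks_from_generator()` then performs every pendant insertion
(several leaves on one edge are ordered along it), discards non-simple
results — a loop must receive at least two insertions — and deduplicates
up to leaf-label-preserving isomorphism.  Enumerating generators on 2, 4
and 6 vertices and checking every resulting two-taxon network by pure
search certifies the level-4 threshold mechanically; the run over 8
vertices (152 networks) finds exactly the non-tree-based level-5
networks, and `find_level5_counterexample()` returns the first in
canonical order.  We deliberately search for the counterexample rather
than hard-coding an adjacency list: any valid counterexample serves all
downstream uses (e.g. `replace_pendant_with_gadget()`, which splices it
into a pendant edge to produce strictly level-$k$ non-tree-based networks
for any $k \ge 5$).

**Random tree-based networks.**  `random_tree_based_network()` draws a
uniform labelled tree topology by sequential leaf insertion into a
uniformly chosen edge, then adds each extra edge by subdividing two
distinct edges of the *extended tree* and joining the subdivision points.
Restricting subdivision to tree-path edges mirrors the biological reading
of reticulation edges as arcs between "vertical" lineages and keeps the
construction tree a verified support-tree witness (returned as an
attribute); networks whose added edges attach to other added edges are
not produced by this generator, which is why tree-basedness of its output
is a guarantee, not a sample property.  The generator emulates topology
only: no branch lengths, no sequence data, no non-binary vertices — so
passing tests certify the combinatorial theory, not inference behaviour
on real alignments.

**Tree enumeration.**  `enumerate_phylo_trees()` builds all
$(2|X|-5)!!$ unrooted binary trees by recursive edge insertion (supported
to $|X| = 6$, i.e. 105 trees), which powers `is_universal()` — the
exhaustive check that every tree on $X$ is a base-tree.  A universal
network's existence for small $X$ is demonstrated constructively by
bounded randomized search (`search_universal_network()`), not by the
known explicit construction, which is outside this package's scope.

## Conventions and degenerate cases

* The single-vertex network on one taxon is valid and is the only
  tree-based single-taxon network.
* `delete_leaf()` may make the suppressed neighbour's two other
  neighbours adjacent twice; the result is then *not* a network and is
  returned as a flagged degenerate object rather than silently accepted —
  a silent multigraph would corrupt every downstream check.
* Leaf labels are opaque strings and distinguish vertices under
  isomorphism; internal vertices are anonymous.  All edge matrices are
  row- and column-sorted, iteration is lexicographic, and tie-breaks
  (e.g. the BFS topological order in the orientation procedure) are
  fixed, so identical inputs give identical outputs everywhere.
* Attaching a taxon to a rooted network (`attach_leaf_at_root()`) adds
  the pendant edge directly at the root, whose outdegree 2 becomes
  undirected degree 3.  An intermediate attachment vertex would have
  degree 2 and violate the network definition; direct attachment also
  makes the operation the exact inverse of the leaf removal in the
  orientation correspondence.
* In the edge-swap property of simple tree-based networks (two incident
  non-pendant base-tree edges at a vertex are connected around it by some
  network edge), the subtrees "beyond" the two edges must be read in the
  support tree, before suppression: the connecting edge may well attach
  to suppressed degree-2 path vertices, and the tests check the property
  in that form.

## Problem sizes and limitations

The package is built for desk-scale, exhaustive verification: generator
enumeration to 8 vertices (level 5), universality to 6 taxa, brute-force
oracles in the tests to 14-vertex networks, and orientation round-trips
over hundreds of seeded random networks — each suite runs in seconds to
a couple of minutes on one CPU.  The exact searches remain correct on
larger inputs but their worst case is exponential (the decision problems
are NP-complete); the `budget` argument turns runaway instances into an
explicit "undecided".  Non-binary networks, branch lengths and any form
of inference from data are out of scope.
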