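# tbnet — tree-based unrooted phylogenetic networks

Phylogenetic networks represent evolutionary histories that are not
tree-like, such as those shaped by horizontal gene transfer or
hybridization. An **unrooted binary phylogenetic network** on a taxon set
*X* is a connected simple graph whose vertices all have degree 1 or 3 and
whose degree-1 vertices are exactly the taxa. The network is
**tree-based** when it contains a **support tree** — a spanning tree whose
leaves are exactly *X* — i.e. when it could have been built by adding
edges into a phylogenetic tree; suppressing the degree-2 vertices of a
support tree yields a **base-tree** on *X*.

`tbnet` is an R package, for phylogenetics researchers and students of
network combinatorics, that makes the structural theory of these networks
computable at desk scale:

* validation and structural analysis: cut-edges and the splits they
  induce, properness, blob (2-edge-connected) decomposition, the induced
  simple networks *B<sub>N</sub>*, strict level and level-*k* checks;
* exact recognition with witnesses: `find_support_tree()`,
  `is_tree_based()`, `enumerate_support_trees()`, base-tree containment
  (`is_based_on()`), displayed trees (`displays()`), fully tree-based
  networks (level-1 characterization plus a definitional verifier);
* the rooted/unrooted correspondence: orienting a tree-based network away
  from a leaf into a rooted tree-based network and back, rooted
  tree-based checking, universality checking;
* the Hamiltonicity reduction *C<sub>e</sub>(x,y)* on cubic graphs
  (Petersen, K4, K3,3 included) that underlies the NP-completeness of
  recognition;
* generators and enumerators: isomorph-free enumeration of the cubic
  multigraph generators of simple level-*k* networks (compiled backend),
  pendant-insertion enumeration of the networks themselves, random
  tree-based networks with verified support-tree witnesses, and
  enumeration of all unrooted binary trees on up to 6 taxa;
* a small command line (`inst/cli/tbnet`): `check`, `orient`, `gen` with
  a scriptable 0/1/2 exit-code contract.

Key structural facts the package both uses and verifies computationally:
every tree-based network is proper; a network is tree-based iff each of
its blob networks is; every proper network of level ≤ 4 is tree-based
while level 5 admits counterexamples; a cubic graph is Hamiltonian iff
its two-leaf reduction is tree-based; and a network is fully tree-based
iff it is level-1.

## Worked example

```r
library(tbnet)

## the classic non-example: subdivide an edge of the Petersen graph and
## attach two leaves
pn <- cubic_to_network(petersen())
pn
#> Unrooted phylogenetic network: 14 vertices, 19 edges, 2 leaves
#> Leaves: x, y
strict_level(pn)       # maximal blob cycle rank
#> [1] 6
is_simple_network(pn)  # all cut-edges trivial
#> [1] TRUE
is_tree_based(pn)      # Petersen is not Hamiltonian, so: no support tree
#> [1] FALSE

## K4 is Hamiltonian, so its reduction is tree-based, with an x-y path
## as support tree and the single-edge tree on {x, y} as base-tree
k4n <- cubic_to_network(complete_graph_k4())
st <- find_support_tree(k4n)
st
#> Support tree: 8 vertices, 7 edges, leaves: x, y
base_tree_of(k4n, st)
#> Unrooted phylogenetic network: 2 vertices, 1 edges, 2 leaves
#> Leaves: x, y
#> The network is a tree.

## orient away from leaf x: a rooted tree-based network on {y} whose
## root is x's former neighbour
r <- orient_from_support_tree(k4n, "x", st)
r$rooted
#> Rooted phylogenetic network: 7 vertices, 9 arcs, root 's1', 1 leaf (y)
is_rooted_tree_based(r$rooted)
#> [1] TRUE
```

The strict level 6 is the cycle rank of the Petersen blob
(19 − 2 pendant edges = 17 edges, 12 vertices, 17 − 12 + 1 = 6); the
`FALSE` from `is_tree_based()` is decided by exact backtracking search
over spanning trees with prescribed leaf set. See the vignette
(`vignettes/tree-based-networks.Rmd`) for the algorithms and design
choices.

Command-line equivalents:

```sh
Rscript inst/cli/tbnet gen cubic --name petersen --out petersen.unet
Rscript inst/cli/tbnet check petersen.unet --mode tree-based   # exit 1
Rscript inst/cli/tbnet check petersen.unet --mode level        # strict_level: 6
```

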