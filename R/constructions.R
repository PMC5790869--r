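## Generators, named graphs and enumeration engines used to exercise the
## structural theory of tree-based networks at desk scale.

#' Cubic graphs
#'
#' A cubic graph is a simple connected graph in which every vertex has
#' degree exactly 3, so `|E| = 3|V|/2` and `|V|` is even.  [petersen()]
#' returns the Petersen graph in its Kneser construction (vertices are the
#' 2-subsets of 1..5, edges join disjoint pairs); it is 3-edge-connected,
#' has girth 5 and is not Hamiltonian.  [complete_graph_k4()] and
#' [complete_bipartite_k33()] are the two smallest interesting Hamiltonian
#' cubic graphs.
#'
#' @param edges two-column character matrix of edges
#' @return an object of class `"cubic_graph"` with components `vertices`
#'   and `edges`
#' @export
cubic_graph <- function(edges) {
  em <- canonical_edges(edges)
  if (any(em[, 1L] == em[, 2L])) stop("loops are not allowed in a cubic graph")
  if (anyDuplicated(edge_keys(em))) stop("parallel edges are not allowed")
  verts <- sort(unique(as.vector(em)))
  deg <- vertex_degrees(verts, em)
  if (any(deg != 3L)) stop("every vertex of a cubic graph must have degree 3")
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  if (!igraph::is_connected(g)) stop("cubic graph must be connected")
  structure(list(vertices = verts, edges = em), class = "cubic_graph")
}

#' @export
print.cubic_graph <- function(x, ...) {
  cat(sprintf("Cubic graph: %d vertices, %d edges\n",
              length(x$vertices), nrow(x$edges)))
  invisible(x)
}

#' @rdname cubic_graph
#' @export
petersen <- function() {
  pairs <- utils::combn(5L, 2L)
  labs <- apply(pairs, 2L, function(p) paste0("p", p[1L], p[2L]))
  em <- empty_edge_matrix()
  for (i in seq_len(ncol(pairs))) {
    for (j in seq_len(ncol(pairs))) {
      if (i < j && length(intersect(pairs[, i], pairs[, j])) == 0L) {
        em <- rbind(em, c(labs[i], labs[j]))
      }
    }
  }
  cubic_graph(em)
}

#' @rdname cubic_graph
#' @export
complete_graph_k4 <- function() {
  cubic_graph(t(utils::combn(c("a", "b", "c", "d"), 2L)))
}

#' @rdname cubic_graph
#' @export
complete_bipartite_k33 <- function() {
  cubic_graph(as.matrix(expand.grid(c("a1", "a2", "a3"), c("b1", "b2", "b3"),
                                    stringsAsFactors = FALSE)))
}

#' The two-leaf network of a cubic graph
#'
#' Subdivides the chosen edge of a cubic graph twice and attaches pendant
#' leaves to the two subdivision vertices.  The result `C_e(x,y)` is a
#' simple network on two taxa whose strict level equals the cycle rank of
#' the cubic graph (`|V|/2 + 1`); the cubic graph is Hamiltonian if and
#' only if `C_e(x,y)` is tree-based for some edge `e`, which for a 3-edge
#' connected `C` happens if and only if it is tree-based for every edge.
#'
#' @param cg a `cubic_graph`
#' @param e an edge of `cg` (length-2 character vector); defaults to the
#'   first edge in canonical order
#' @param leaves labels for the two new taxa
#' @return a `phynet` on the two new taxa
#' @export
cubic_to_network <- function(cg, e = NULL, leaves = c("x", "y")) {
  stopifnot(inherits(cg, "cubic_graph"), length(leaves) == 2L)
  if (is.null(e)) e <- cg$edges[1L, ]
  e <- as.character(e)
  if (!(edge_key(e[1L], e[2L]) %in% edge_keys(cg$edges))) {
    stop("'e' is not an edge of the cubic graph")
  }
  if (any(leaves %in% cg$vertices)) stop("leaf labels collide with vertex labels")
  sub <- fresh_labels(c(cg$vertices, leaves), 2L, prefix = "s")
  em <- edges_minus(cg$edges, rbind(e))
  phynet(rbind(em,
               c(e[1L], sub[1L]), c(sub[1L], sub[2L]), c(sub[2L], e[2L]),
               c(sub[1L], leaves[1L]), c(sub[2L], leaves[2L])),
         leaves = leaves)
}

## ---- Hamiltonicity (exact backtracking) ----

adjacency_list <- function(verts, em) {
  adj <- lapply(stats::setNames(vector("list", length(verts)), verts),
                function(z) character(0))
  for (i in seq_len(nrow(em))) {
    adj[[em[i, 1L]]] <- c(adj[[em[i, 1L]]], em[i, 2L])
    adj[[em[i, 2L]]] <- c(adj[[em[i, 2L]]], em[i, 1L])
  }
  lapply(adj, sort)
}

# Hamiltonian path from `from` to `to` visiting every vertex; NULL if none.
hamiltonian_path <- function(verts, adj, from, to) {
  n <- length(verts)
  visited <- stats::setNames(logical(n), verts)
  path <- character(n)
  recurse <- function(v, depth) {
    visited[v] <<- TRUE
    path[depth] <<- v
    if (depth == n) {
      if (v == to) return(TRUE)
    } else {
      for (w in adj[[v]]) {
        if (!visited[w] && (w != to || depth == n - 1L)) {
          if (recurse(w, depth + 1L)) return(TRUE)
        }
      }
    }
    visited[v] <<- FALSE
    FALSE
  }
  if (recurse(from, 1L)) path else NULL
}

#' Hamiltonian cycles in cubic graphs
#'
#' `hamiltonian_cycle_through()` searches for a Hamiltonian cycle using the
#' given edge (returned as the vertex sequence, closing edge implicit);
#' `is_hamiltonian()` asks for any Hamiltonian cycle.  Exact backtracking
#' search.
#'
#' @param cg a `cubic_graph`
#' @param e an edge of `cg`
#' @return `hamiltonian_cycle_through()`: character vector of vertices or
#'   `NULL`; `is_hamiltonian()`: logical
#' @export
hamiltonian_cycle_through <- function(cg, e) {
  stopifnot(inherits(cg, "cubic_graph"))
  e <- as.character(e)
  if (!(edge_key(e[1L], e[2L]) %in% edge_keys(cg$edges))) {
    stop("'e' is not an edge of the cubic graph")
  }
  adj <- adjacency_list(cg$vertices, cg$edges)
  hamiltonian_path(cg$vertices, adj, e[1L], e[2L])
}

#' @rdname hamiltonian_cycle_through
#' @export
is_hamiltonian <- function(cg) {
  stopifnot(inherits(cg, "cubic_graph"))
  # every Hamiltonian cycle uses 2 of the 3 edges at the first vertex,
  # so it suffices to look for cycles through edges at one vertex
  v <- cg$vertices[1L]
  adj <- adjacency_list(cg$vertices, cg$edges)
  for (w in adj[[v]]) {
    if (!is.null(hamiltonian_cycle_through(cg, c(v, w)))) return(TRUE)
  }
  FALSE
}

## ---- cubic multigraph generators ----

#' Enumerate connected cubic multigraphs
#'
#' Enumerates, up to isomorphism, all connected multigraphs on `n` vertices
#' in which every vertex has degree 3 (a loop contributing 2).  These are
#' the generators of simple level-k networks: every simple level-k network
#' arises by inserting pendant leaf edges into the edges of such a
#' multigraph on `2k - 2` vertices.  The backend enumerates labelled
#' multiplicity matrices in C++ and deduplicates with colour-refinement
#' invariants plus exact backtracking isomorphism.
#'
#' @param n even number of vertices, between 2 and 8
#' @return list of objects of class `"cubic_multigraph"`, each with
#'   components `n`, `vertices` (`m1 ... mn`), `edges` (two-column matrix
#'   with repeated rows for parallel edges and `c(v, v)` rows for loops)
#'   and `mult` (the multiplicity matrix, loops on the diagonal); the order
#'   is deterministic
#' @export
enumerate_cubic_multigraphs <- function(n) {
  n <- as.integer(n)
  if (n %% 2L != 0L || n < 2L) stop("'n' must be even and at least 2")
  if (n > 8L) stop("enumeration supported up to n = 8")
  mats <- enum_cubic_multigraphs_cpp(n)
  lapply(mats, multigraph_from_mult)
}

multigraph_from_mult <- function(mult) {
  n <- nrow(mult)
  verts <- paste0("m", seq_len(n))
  em <- empty_edge_matrix()
  for (i in seq_len(n)) {
    if (mult[i, i] > 0L) {
      em <- rbind(em, matrix(rep(verts[i], 2L * mult[i, i]), ncol = 2L, byrow = TRUE))
    }
    for (j in seq_len(n)) {
      if (j > i && mult[i, j] > 0L) {
        em <- rbind(em, matrix(rep(c(verts[i], verts[j]), mult[i, j]),
                               ncol = 2L, byrow = TRUE))
      }
    }
  }
  structure(list(n = n, vertices = verts, edges = em, mult = mult),
            class = "cubic_multigraph")
}

#' @export
print.cubic_multigraph <- function(x, ...) {
  n_loops <- sum(diag(x$mult))
  cat(sprintf("Cubic multigraph: %d vertices, %d edges (%d loop%s)\n",
              x$n, nrow(x$edges), n_loops, if (n_loops == 1L) "" else "s"))
  invisible(x)
}

#' Simple networks from a generator multigraph
#'
#' Produces all simple networks obtainable by inserting the given pendant
#' leaves into the edges of a cubic multigraph: each insertion subdivides
#' an edge and hangs the leaf from the subdivision vertex; several leaves
#' on one edge are ordered along it.  Results that are not valid simple
#' networks are discarded (in particular a loop must receive at least two
#' insertions, and a parallel class must lose its multiplicity), and the
#' survivors are deduplicated up to leaf-label-preserving isomorphism.
#' Every output has strict level equal to the cycle rank of the generator.
#'
#' @param gen a `cubic_multigraph`
#' @param leaves character vector of at least two taxon labels
#' @return list of `phynet` objects, deterministic order
#' @export
networks_from_generator <- function(gen, leaves) {
  stopifnot(inherits(gen, "cubic_multigraph"))
  leaves <- as.character(leaves)
  if (length(leaves) < 2L) stop("at least two leaves are required")
  slots <- gen$edges                       # one row per edge copy
  s <- nrow(slots)
  l <- length(leaves)
  kept <- list()
  kept_inv <- character(0)
  assignment <- integer(l)
  consider <- function(ordered_by_slot) {
    em <- empty_edge_matrix()
    for (k in seq_len(s)) {
      a <- slots[k, 1L]; b <- slots[k, 2L]
      on_slot <- ordered_by_slot[[k]]
      if (length(on_slot) == 0L) {
        if (a == b) return(invisible())        # untouched loop: never simple
        em <- rbind(em, c(a, b))
      } else {
        pts <- paste0("s", k, "p", seq_along(on_slot))
        chain <- c(a, pts, b)
        for (q in seq_len(length(chain) - 1L)) {
          em <- rbind(em, c(chain[q], chain[q + 1L]))
        }
        em <- rbind(em, cbind(pts, on_slot))
      }
    }
    if (any(em[, 1L] == em[, 2L])) return(invisible())
    if (anyDuplicated(edge_keys(canonical_edges(em)))) return(invisible())
    net <- tryCatch(phynet(em), error = function(e) NULL)
    if (is.null(net)) return(invisible())
    if (!setequal(net$leaves, leaves)) return(invisible())
    if (!is_simple_network(net)) return(invisible())
    inv <- leafdist_invariant(net)
    for (i in seq_along(kept)) {
      if (kept_inv[i] == inv && phynet_isomorphic(kept[[i]], net)) {
        return(invisible())
      }
    }
    kept[[length(kept) + 1L]] <<- net
    kept_inv <<- c(kept_inv, inv)
    invisible()
  }
  orderings <- function(grp) {
    # all orderings of the leaves assigned to one slot
    if (length(grp) <= 1L) return(list(grp))
    perms <- permutations_of(grp)
    perms
  }
  recurse_assign <- function(k) {
    if (k > l) {
      by_slot <- split(leaves, factor(assignment, levels = seq_len(s)))
      ord_options <- lapply(by_slot, orderings)
      expand_orderings(ord_options, consider)
      return(invisible())
    }
    for (slot in seq_len(s)) {
      assignment[k] <<- slot
      recurse_assign(k + 1L)
    }
    invisible()
  }
  recurse_assign(1L)
  kept
}

permutations_of <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

expand_orderings <- function(options, fun, prefix = list()) {
  if (length(prefix) == length(options)) {
    fun(prefix)
    return(invisible())
  }
  k <- length(prefix) + 1L
  for (opt in options[[k]]) {
    expand_orderings(options, fun, c(prefix, list(opt)))
  }
  invisible()
}

# cheap leaf-labelled isomorphism invariant: sorted rows of leaf distances
leafdist_invariant <- function(net) {
  g <- as_igraph_phynet(net)
  d <- igraph::distances(g, v = net$leaves)
  rows <- apply(d, 2L, function(col) paste(col, collapse = ","))
  paste(sort(rows), collapse = ";")
}

## ---- random tree-based networks and tree enumeration ----

#' Random tree-based network
#'
#' Draws a random phylogenetic tree on the given taxa (uniform over labelled
#' topologies, by sequential leaf insertion into a uniformly chosen edge)
#' and then adds `extra_edges` edges, each subdividing two distinct edges of
#' the current network and joining the two subdivision vertices.  The
#' result is tree-based by construction; the construction tree (extended
#' through the subdivision vertices) is attached as attribute
#' `"support_tree"` and verifies as a support tree.
#'
#' @param x taxon labels (at least one)
#' @param extra_edges number of edges to add (default 0: a random tree)
#' @param seed optional integer; if given, `set.seed(seed)` is called first
#'   so identical inputs give identical networks
#' @return a `phynet` with attribute `support_tree`
#' @export
random_tree_based_network <- function(x, extra_edges = 0L, seed = NULL) {
  x <- sort(as.character(x))
  if (anyDuplicated(x)) stop("taxon labels must be distinct")
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  if (n == 0L) stop("need at least one taxon")
  if (n == 1L) {
    if (extra_edges > 0L) stop("cannot add edges to a single-vertex network")
    return(structure(phynet(vertices = x)))
  }
  tlabs <- fresh_labels(x, max(0L, n - 2L) + 2L * extra_edges, prefix = "t")
  if (n == 2L) {
    em <- rbind(x)
  } else {
    em <- rbind(c(x[1L], tlabs[1L]), c(x[2L], tlabs[1L]), c(x[3L], tlabs[1L]))
    for (k in seq_len(n - 3L)) {
      i <- sample.int(nrow(em), 1L)
      mid <- tlabs[k + 1L]
      e <- em[i, ]
      em <- rbind(em[-i, , drop = FALSE],
                  c(e[1L], mid), c(mid, e[2L]), c(mid, x[k + 3L]))
    }
  }
  rlabs <- tlabs[seq_len(2L * extra_edges) + max(0L, n - 2L)]
  # edges of the (extended) tree: only these are subdivided, so the tree
  # grown through the subdivision vertices stays a support-tree witness
  tree_rows <- seq_len(nrow(em))
  join_edges <- empty_edge_matrix()
  for (j in seq_len(extra_edges)) {
    if (length(tree_rows) < 2L) {
      stop("not enough tree edges to add an extra edge between two distinct edges")
    }
    picks <- sort(sample(tree_rows, 2L))
    a <- em[picks[1L], ]; b <- em[picks[2L], ]
    va <- rlabs[2L * j - 1L]; vb <- rlabs[2L * j]
    keep <- setdiff(seq_len(nrow(em)), picks)
    tree_rows <- match(setdiff(tree_rows, picks), keep)
    em <- rbind(em[keep, , drop = FALSE],
                c(a[1L], va), c(va, a[2L]),
                c(b[1L], vb), c(vb, b[2L]),
                c(va, vb))
    tree_rows <- c(tree_rows, nrow(em) - 4L:1L)  # the four half-edges
    join_edges <- rbind(join_edges, c(va, vb))
  }
  net <- phynet(em, leaves = x)
  st <- new_support_tree(net, edges_minus(net$edges, join_edges))
  stopifnot(is_support_tree(net, st))
  attr(net, "support_tree") <- st
  net
}

#' Enumerate unrooted binary phylogenetic trees
#'
#' All distinct phylogenetic trees on the taxon set, by sequential
#' insertion; there are `(2|X|-5)!!` of them for `|X| >= 3` (1, 3, 15, 105
#' for 3..6 taxa) and a single degenerate tree for 1 or 2 taxa.
#'
#' @param x taxon labels, between 1 and 6 of them
#' @return list of `phynet` objects that are trees
#' @export
enumerate_phylo_trees <- function(x) {
  x <- sort(as.character(x))
  n <- length(x)
  if (n < 1L || n > 6L) stop("supported for 1 to 6 taxa")
  if (n == 1L) return(list(phynet(vertices = x)))
  if (n == 2L) return(list(phynet(rbind(x))))
  trees <- list(rbind(c(x[1L], "i1"), c(x[2L], "i1"), c(x[3L], "i1")))
  for (k in seq_len(n - 3L)) {
    mid <- paste0("i", k + 1L)
    nxt <- list()
    for (em in trees) {
      em <- canonical_edges(em)
      for (i in seq_len(nrow(em))) {
        e <- em[i, ]
        nxt[[length(nxt) + 1L]] <- rbind(em[-i, , drop = FALSE],
                                         c(e[1L], mid), c(mid, e[2L]),
                                         c(mid, x[k + 3L]))
      }
    }
    trees <- nxt
  }
  lapply(trees, phynet)
}

## ---- the level-5 counterexample and the pendant gadget ----

tbnet_cache <- new.env(parent = emptyenv())

#' Find a non-tree-based proper network of minimal level
#'
#' Exhaustively searches the simple networks on two taxa produced by the
#' cubic multigraph generators on 8 vertices (strict level 5) and returns
#' the first one, in canonical enumeration order, that is not tree-based.
#' Its existence is a structural fact (proper networks of level at most 4
#' are always tree-based, so 5 is the minimal level at which the search can
#' succeed); failure to find one signals an implementation bug and raises
#' an error.  The result is cached for the session.
#'
#' @return a `phynet` on `{x, y}`: simple, proper, strict level 5, not
#'   tree-based
#' @export
find_level5_counterexample <- function() {
  if (!is.null(tbnet_cache$level5)) return(tbnet_cache$level5)
  for (gen in enumerate_cubic_multigraphs(8L)) {
    for (net in networks_from_generator(gen, c("x", "y"))) {
      if (is.null(find_support_tree(net))) {
        stopifnot(strict_level(net) == 5L, is_proper(net),
                  is_simple_network(net))
        tbnet_cache$level5 <- net
        return(net)
      }
    }
  }
  stop("internal error: no level-5 counterexample found in the enumeration")
}

#' Replace a pendant edge by a two-leaf gadget network
#'
#' Splices a two-taxon network (the gadget) into a pendant edge of `net`:
#' the pendant edge is removed, the gadget loses its two leaves, the
#' gadget-side neighbour of its first leaf is joined to the former interior
#' endpoint of the pendant edge, and the neighbour of its second leaf is
#' joined to the taxon, which keeps its label.  Splicing a non-tree-based
#' gadget of level k makes the result non-tree-based while leaving the
#' level at `max(level(net), k)`; with the single-edge gadget the network
#' is returned unchanged.
#'
#' @param net a `phynet` object
#' @param leaf a taxon of `net` whose pendant edge is replaced
#' @param gadget a `phynet` on exactly two taxa
#' @return a `phynet` with the same taxon set as `net`
#' @export
replace_pendant_with_gadget <- function(net, leaf, gadget) {
  stopifnot(is_phynet(net), is_phynet(gadget))
  if (!(leaf %in% net$leaves)) stop("'", leaf, "' is not a leaf of the network")
  if (length(gadget$leaves) != 2L) stop("gadget must have exactly two leaves")
  if (length(gadget$vertices) == 2L) return(net)   # single-edge gadget: identity
  u <- leaf_neighbour(net, leaf)
  gl <- gadget$leaves
  internal <- setdiff(gadget$vertices, gl)
  fresh <- fresh_labels(c(net$vertices, "g"), length(internal), prefix = "g")
  map <- stats::setNames(fresh, internal)
  gx_nb <- map[[leaf_neighbour(gadget, gl[1L])]]
  gy_nb <- map[[leaf_neighbour(gadget, gl[2L])]]
  gem <- edges_minus(gadget$edges,
                     rbind(c(gl[1L], leaf_neighbour(gadget, gl[1L])),
                           c(gl[2L], leaf_neighbour(gadget, gl[2L]))))
  gem[] <- map[gem]
  em <- rbind(edges_minus(net$edges, rbind(c(leaf, u))),
              gem, c(u, gx_nb), c(gy_nb, leaf))
  out <- phynet(em, leaves = net$leaves)
  out
}

#' Named fixture networks
#'
#' Canonical networks used throughout the examples and the command line:
#' `petersen_net` (the Petersen reduction `P_e(x,y)`: simple, strict level
#' 6, not tree-based), `k4_net` (`K4_e(x,y)`: strict level 3, tree-based),
#' `level2_unique` (the unique simple level-2 network on two taxa),
#' `level5_counterexample` (see [find_level5_counterexample()]) and
#' `triangle3` (a triangle with a pendant leaf on each corner: level 1,
#' fully tree-based).
#'
#' @param name one of the fixture names above
#' @return a `phynet` object
#' @export
named_fixture <- function(name = c("petersen_net", "k4_net", "level2_unique",
                                   "level5_counterexample", "triangle3")) {
  name <- match.arg(name)
  switch(name,
    petersen_net = cubic_to_network(petersen()),
    k4_net = cubic_to_network(complete_graph_k4()),
    level2_unique = {
      gens <- enumerate_cubic_multigraphs(2L)
      nets <- unlist(lapply(gens, networks_from_generator,
                            leaves = c("x", "y")), recursive = FALSE)
      stopifnot(length(nets) == 1L)
      nets[[1L]]
    },
    level5_counterexample = find_level5_counterexample(),
    triangle3 = phynet(rbind(c("u1", "u2"), c("u2", "u3"), c("u1", "u3"),
                             c("a", "u1"), c("b", "u2"), c("c", "u3")))
  )
}
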