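## Exact recognition of tree-based networks and related properties.
##
## The workhorse is a depth-first edge-inclusion backtracking search over
## tree subgraphs, with degree pruning: cut-edges are forced into every
## spanning tree, and a branch dies as soon as an internal vertex can no
## longer reach degree >= 2 (spanning mode) or is stranded at degree 1
## (subtree mode).  NP-complete questions are answered exactly; instances of
## interest are small and the blob-wise decomposition bounds the blowup to
## single blobs.

budget_error <- function() {
  stop(structure(class = c("tbnet_budget_error", "error", "condition"),
                 list(message = "search budget exceeded (result undecided)",
                      call = NULL)))
}

# Backtracking search over tree subgraphs of `net`.
#   spanning = TRUE : spanning trees whose degree-1 vertices are exactly X
#   spanning = FALSE: subtrees (acyclic connected subgraphs) whose degree-1
#                     vertices are exactly X
# `accept(edge_matrix)` filters hits; search stops after `limit` accepted
# hits or when `budget` search nodes have been expanded.  Hits are returned
# as canonical edge matrices in a deterministic order (edges considered in
# lexicographic order, inclusion branch first).
tree_subgraph_search <- function(net, spanning = TRUE, limit = 1L,
                                 budget = Inf, accept = NULL) {
  verts <- net$vertices
  n <- length(verts)
  em <- net$edges
  m <- nrow(em)
  if (n == 1L) {
    hit <- empty_edge_matrix()
    if (is.null(accept) || isTRUE(accept(hit))) return(list(hit))
    return(list())
  }
  e1 <- match(em[, 1L], verts)
  e2 <- match(em[, 2L], verts)
  is_leaf <- verts %in% net$leaves
  ce_keys <- edge_keys(cut_edges(net))
  forced <- if (spanning) {
    which(edge_keys(em) %in% ce_keys)
  } else {
    which(is_leaf[e1] | is_leaf[e2])  # every taxon's pendant edge is used
  }
  undecided <- setdiff(seq_len(m), forced)

  uf_find <- function(parent, x) {
    while (parent[x] != x) x <- parent[x]
    x
  }

  parent0 <- seq_len(n)
  deg0 <- integer(n)
  for (i in forced) {
    ru <- uf_find(parent0, e1[i]); rv <- uf_find(parent0, e2[i])
    if (ru == rv) return(list())   # forced edges contain a cycle: impossible
    parent0[ru] <- rv
    deg0[e1[i]] <- deg0[e1[i]] + 1L
    deg0[e2[i]] <- deg0[e2[i]] + 1L
  }
  avail0 <- integer(n)
  for (i in undecided) {
    avail0[e1[i]] <- avail0[e1[i]] + 1L
    avail0[e2[i]] <- avail0[e2[i]] + 1L
  }
  if (spanning && any(!is_leaf & deg0 + avail0 < 2L)) return(list())

  state <- new.env(parent = emptyenv())
  state$hits <- list()
  state$nodes <- 0L
  state$done <- FALSE
  nu <- length(undecided)

  finalize <- function(parent, deg, chosen, included) {
    used <- which(deg > 0L)
    if (spanning) {
      if (chosen != n - 1L) return(invisible())
    } else {
      if (length(used) == 0L) return(invisible())
      if (any(!is_leaf[used] & deg[used] == 1L)) return(invisible())
      roots <- unique(vapply(used, function(v) uf_find(parent, v), integer(1)))
      if (length(roots) != 1L) return(invisible())
    }
    hit <- em[sort(c(forced, included)), , drop = FALSE]
    if (is.null(accept) || isTRUE(accept(hit))) {
      state$hits[[length(state$hits) + 1L]] <- hit
      if (length(state$hits) >= limit) state$done <- TRUE
    }
    invisible()
  }

  recurse <- function(pos, parent, deg, avail, chosen, included) {
    if (state$done) return(invisible())
    state$nodes <- state$nodes + 1L
    if (state$nodes > budget) budget_error()
    if (pos > nu) {
      finalize(parent, deg, chosen, included)
      return(invisible())
    }
    if (spanning && chosen + (nu - pos + 1L) < n - 1L) return(invisible())
    i <- undecided[pos]
    u <- e1[i]; v <- e2[i]
    avail[u] <- avail[u] - 1L
    avail[v] <- avail[v] - 1L
    # branch 1: include edge i
    if (!(spanning && chosen >= n - 1L)) {
      ru <- uf_find(parent, u); rv <- uf_find(parent, v)
      if (ru != rv) {
        p2 <- parent; p2[ru] <- rv
        d2 <- deg
        d2[u] <- d2[u] + 1L; d2[v] <- d2[v] + 1L
        recurse(pos + 1L, p2, d2, avail, chosen + 1L, c(included, i))
      }
    }
    if (state$done) return(invisible())
    # branch 2: exclude edge i
    feas <- TRUE
    for (w in c(u, v)) {
      if (is_leaf[w]) next
      if (spanning) {
        if (deg[w] + avail[w] < 2L) { feas <- FALSE; break }
      } else {
        if (deg[w] == 1L && avail[w] == 0L) { feas <- FALSE; break }
        if (deg[w] >= 2L) next
      }
    }
    if (feas) recurse(pos + 1L, parent, deg, avail, chosen, included)
    invisible()
  }

  recurse(1L, parent0, deg0, avail0, length(forced), integer(0))
  state$hits
}

new_support_tree <- function(net, edges) {
  structure(list(vertices = net$vertices, edges = canonical_edges(edges),
                 leaves = net$leaves),
            class = "support_tree")
}

#' @export
print.support_tree <- function(x, ...) {
  cat(sprintf("Support tree: %d vertices, %d edges, leaves: %s\n",
              length(x$vertices), nrow(x$edges),
              paste(x$leaves, collapse = ", ")))
  invisible(x)
}

#' Verify a support tree
#'
#' Checks that `st` is a spanning tree of `net` whose degree-1 vertices are
#' exactly the taxa of `net`.
#'
#' @param net a `phynet` object
#' @param st a `support_tree` object or two-column edge matrix
#' @return logical
#' @export
is_support_tree <- function(net, st) {
  em <- canonical_edges(if (inherits(st, "support_tree")) st$edges else st)
  if (length(net$vertices) == 1L) return(nrow(em) == 0L)
  if (nrow(em) != length(net$vertices) - 1L) return(FALSE)
  if (!all(edge_keys(em) %in% edge_keys(net$edges))) return(FALSE)
  verts <- sort(unique(as.vector(em)))
  if (!identical(verts, net$vertices)) return(FALSE)
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  if (!igraph::is_connected(g)) return(FALSE)  # n-1 edges + connected => tree
  deg <- vertex_degrees(verts, em)
  identical(sort(verts[deg == 1L]), net$leaves)
}

#' Find a support tree
#'
#' Searches for a spanning tree of the network whose leaves are exactly the
#' taxon set.  The search decomposes blob-wise: a network is tree-based if
#' and only if every induced simple network `B_N` is, and every cut-edge
#' belongs to every support tree, so per-blob support trees are found
#' independently and spliced together with the cut-edges.
#'
#' @param net a `phynet` object
#' @param budget maximum number of search nodes to expand before raising a
#'   `tbnet_budget_error` (undecided — never reported as "no")
#' @param decompose solve per blob (default); `FALSE` runs a single
#'   whole-network search
#' @return a `support_tree` object, or `NULL` if the network is not
#'   tree-based
#' @export
find_support_tree <- function(net, budget = Inf, decompose = TRUE) {
  stopifnot(is_phynet(net))
  if (length(net$vertices) == 1L) return(new_support_tree(net, empty_edge_matrix()))
  if (is_phynet_tree(net)) return(new_support_tree(net, net$edges))
  if (!decompose) {
    hits <- tree_subgraph_search(net, spanning = TRUE, limit = 1L, budget = budget)
    if (length(hits) == 0L) return(NULL)
    return(new_support_tree(net, hits[[1L]]))
  }
  tree_edges <- cut_edges(net)
  for (b in blobs(net)) {
    bn <- blob_network(net, b)
    hits <- tree_subgraph_search(bn, spanning = TRUE, limit = 1L, budget = budget)
    if (length(hits) == 0L) return(NULL)
    tree_edges <- rbind(tree_edges, edges_in(hits[[1L]], edge_keys(b$edges)))
  }
  st <- new_support_tree(net, tree_edges)
  stopifnot(is_support_tree(net, st))
  st
}

#' Is a network tree-based?
#'
#' A network is tree-based if it has a support tree.  With
#' `use_shortcuts = TRUE` (default) three structural facts short-circuit the
#' search: a single-taxon network is tree-based only if it is the single
#' vertex; a network that is not proper is never tree-based; and every
#' proper network of strict level at most 4 is tree-based.  With
#' `use_shortcuts = FALSE` the verdict comes from the search alone (useful
#' when those facts are themselves being verified).
#'
#' @inheritParams find_support_tree
#' @param use_shortcuts apply the structural shortcuts (default `TRUE`)
#' @return logical
#' @export
is_tree_based <- function(net, budget = Inf, use_shortcuts = TRUE) {
  stopifnot(is_phynet(net))
  if (length(net$leaves) == 1L) return(length(net$vertices) == 1L)
  if (use_shortcuts) {
    if (!is_proper(net)) return(FALSE)
    if (strict_level(net) <= 4L) return(TRUE)
  }
  !is.null(find_support_tree(net, budget = budget))
}

#' Enumerate support trees
#'
#' Enumerates distinct support trees (as edge sets) of a network, in a
#' deterministic order, up to `limit`.
#'
#' @inheritParams find_support_tree
#' @param limit maximum number of support trees to return
#' @return list of `support_tree` objects
#' @export
enumerate_support_trees <- function(net, limit = Inf, budget = Inf) {
  stopifnot(is_phynet(net))
  if (length(net$vertices) == 1L) {
    return(list(new_support_tree(net, empty_edge_matrix())))
  }
  hits <- tree_subgraph_search(net, spanning = TRUE, limit = limit, budget = budget)
  lapply(hits, function(h) new_support_tree(net, h))
}

# suppress every degree-2 vertex of an acyclic edge set
suppress_degree2 <- function(em) {
  repeat {
    verts <- sort(unique(as.vector(em)))
    deg <- vertex_degrees(verts, em)
    v2 <- verts[deg == 2L]
    if (length(v2) == 0L) return(canonical_edges(em))
    v <- v2[1L]
    touch <- em[, 1L] == v | em[, 2L] == v
    nbrs <- setdiff(as.vector(em[touch, , drop = FALSE]), v)
    em <- rbind(em[!touch, , drop = FALSE], nbrs)
  }
}

#' Base-tree of a support tree
#'
#' The base-tree is the phylogenetic tree obtained from a support tree by
#' suppressing all its degree-2 vertices; the leaf set is unchanged.
#'
#' @param net a `phynet` object
#' @param st a support tree of `net`
#' @return a `phynet` object that is a phylogenetic tree on the taxa of `net`
#' @export
base_tree_of <- function(net, st) {
  if (!is_support_tree(net, st)) stop("not a support tree of the network")
  em <- if (inherits(st, "support_tree")) st$edges else canonical_edges(st)
  if (nrow(em) == 0L) return(phynet(vertices = net$vertices))
  out <- phynet(suppress_degree2(em))
  stopifnot(is_phynet_tree(out), identical(out$leaves, net$leaves))
  out
}

#' Base-tree containment
#'
#' Decides whether the network is based on the tree `tree`: whether some
#' support tree of `net` suppresses to a tree isomorphic to `tree` with leaf
#' labels fixed.  Exact search (the problem is NP-complete in general).
#'
#' @param net a `phynet` object
#' @param tree a `phynet` object that is a phylogenetic tree on the same
#'   taxon set
#' @param budget search-node budget, see [find_support_tree()]
#' @return logical
#' @export
is_based_on <- function(net, tree, budget = Inf) {
  stopifnot(is_phynet(net), is_phynet_tree(tree))
  if (!setequal(net$leaves, tree$leaves)) {
    stop("network and tree must share the same taxon set")
  }
  if (length(net$vertices) == 1L) return(length(tree$vertices) == 1L)
  if (length(tree$vertices) == 1L) return(FALSE)
  hits <- tree_subgraph_search(
    net, spanning = TRUE, limit = 1L, budget = budget,
    accept = function(h) {
      phynet_isomorphic(base_tree_of(net, new_support_tree(net, h)), tree)
    })
  length(hits) > 0L
}

#' Displayed trees
#'
#' Decides whether `tree` is displayed by the network: whether some subtree
#' of `net` (not necessarily spanning) with leaf set equal to the taxa
#' suppresses to a tree isomorphic to `tree` with leaf labels fixed.  A tree
#' may be displayed without being a base-tree.
#'
#' @inheritParams is_based_on
#' @return logical
#' @export
displays <- function(net, tree, budget = Inf) {
  stopifnot(is_phynet(net), is_phynet_tree(tree))
  if (!setequal(net$leaves, tree$leaves)) {
    stop("network and tree must share the same taxon set")
  }
  if (length(net$leaves) == 1L) return(length(tree$vertices) == 1L)
  hits <- tree_subgraph_search(
    net, spanning = FALSE, limit = 1L, budget = budget,
    accept = function(h) phynet_isomorphic(phynet(suppress_degree2(h)), tree))
  length(hits) > 0L
}

#' Fully tree-based networks
#'
#' A network is fully tree-based if every subtree with leaf set equal to the
#' taxa is a support tree (i.e. spans the network); this holds exactly for
#' level-1 networks.  `is_fully_tree_based()` returns the level-1
#' characterization; `fully_tree_based_direct()` verifies the definition by
#' exhaustive subtree enumeration (intended for small networks, and tested
#' against the characterization).  A single-vertex subtree on taxon `x`
#' counts as a subtree with leaf set `{x}`, so a one-taxon network larger
#' than a single vertex is not fully tree-based.
#'
#' @inheritParams find_support_tree
#' @return logical
#' @export
is_fully_tree_based <- function(net) {
  stopifnot(is_phynet(net))
  strict_level(net) <= 1L
}

#' @rdname is_fully_tree_based
#' @export
fully_tree_based_direct <- function(net, budget = Inf) {
  stopifnot(is_phynet(net))
  n <- length(net$vertices)
  if (length(net$leaves) == 1L) return(n == 1L)
  non_spanning <- tree_subgraph_search(
    net, spanning = FALSE, limit = 1L, budget = budget,
    accept = function(h) length(unique(as.vector(h))) < n)
  length(non_spanning) == 0L
}
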