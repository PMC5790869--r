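#' Construct and validate a rooted binary phylogenetic network
#'
#' A rooted binary phylogenetic network is a directed acyclic graph with a
#' single root (indegree 0, outdegree 2), leaves (indegree 1, outdegree 0)
#' labelled by the taxa, and all other vertices of total degree 3 (tree
#' vertices with indegree 1/outdegree 2, reticulations with indegree
#' 2/outdegree 1).
#'
#' @param arcs two-column character matrix of arcs (from, to)
#' @return an object of class `"rootednet"` with components `vertices`,
#'   `arcs` (rows sorted), `root` and `leaves`
#' @export
rootednet <- function(arcs) {
  am <- as.matrix(arcs)
  storage.mode(am) <- "character"
  dimnames(am) <- NULL
  if (NROW(am) == 0L || ncol(am) != 2L) stop("arcs must be a two-column matrix")
  if (any(am[, 1L] == am[, 2L])) stop("loops are not allowed")
  if (anyDuplicated(paste(am[, 1L], am[, 2L], sep = "\r"))) {
    stop("parallel arcs are not allowed")
  }
  am <- am[order(am[, 1L], am[, 2L]), , drop = FALSE]
  verts <- sort(unique(as.vector(am)))
  indeg <- as.integer(table(factor(am[, 2L], levels = verts)))
  outdeg <- as.integer(table(factor(am[, 1L], levels = verts)))
  roots <- verts[indeg == 0L]
  if (length(roots) != 1L) stop("there must be exactly one root (indegree 0)")
  if (outdeg[match(roots, verts)] != 2L) stop("the root must have outdegree 2")
  lv <- verts[outdeg == 0L]
  if (length(lv) == 0L) stop("there must be at least one leaf")
  if (any(indeg[match(lv, verts)] != 1L)) stop("leaves must have indegree 1")
  mid <- setdiff(verts, c(roots, lv))
  for (v in mid) {
    i <- indeg[match(v, verts)]; o <- outdeg[match(v, verts)]
    if (!((i == 1L && o == 2L) || (i == 2L && o == 1L))) {
      stop("vertex '", v, "' has indegree ", i, " and outdegree ", o,
           "; expected 1/2 (tree vertex) or 2/1 (reticulation)")
    }
  }
  g <- igraph::graph_from_edgelist(am, directed = TRUE)
  if (!igraph::is_dag(g)) stop("the arc set contains a directed cycle")
  if (!igraph::is_connected(g, mode = "weak")) stop("network must be connected")
  structure(list(vertices = verts, arcs = am, root = roots, leaves = lv),
            class = "rootednet")
}

#' @rdname rootednet
#' @param x object to test
#' @export
is_rootednet <- function(x) inherits(x, "rootednet")

#' @export
print.rootednet <- function(x, ...) {
  cat(sprintf(
    "Rooted phylogenetic network: %d vertices, %d arcs, root '%s', %d %s (%s)\n",
    length(x$vertices), nrow(x$arcs), x$root, length(x$leaves),
    if (length(x$leaves) == 1L) "leaf" else "leaves",
    paste(x$leaves, collapse = ", ")))
  invisible(x)
}

#' Reticulation vertices of a rooted network
#' @param m a `rootednet` object
#' @return character vector of indegree-2 vertices
#' @export
reticulations <- function(m) {
  stopifnot(is_rootednet(m))
  indeg <- table(factor(m$arcs[, 2L], levels = m$vertices))
  sort(m$vertices[indeg == 2L])
}

#' Orient a tree-based network into a rooted network
#'
#' Implements the orientation procedure relating unrooted and rooted
#' tree-based networks: orient the support tree `st` away from leaf `x`,
#' visit the vertices in that order (breadth-first from `x`,
#' lexicographic tie-break) and direct every not-yet-oriented non-tree edge
#' away from the vertex visited earlier.  Removing `x` and its pendant edge
#' then leaves a rooted tree-based network on the remaining taxa whose root
#' is the former neighbour of `x`.
#'
#' @param net a `phynet` object with at least two taxa (and at least one
#'   internal vertex, i.e. not the single-edge network)
#' @param x a leaf of `net`
#' @param st a support tree of `net`; defaults to `find_support_tree(net)`
#' @return a list with components `orientation` (two-column matrix: every
#'   edge of `net` as an arc) and `rooted` (a validated `rootednet` on the
#'   taxa minus `x`)
#' @export
orient_from_support_tree <- function(net, x, st = NULL) {
  stopifnot(is_phynet(net))
  if (!(x %in% net$leaves)) stop("'", x, "' is not a leaf of the network")
  if (length(net$leaves) < 2L) stop("need at least two taxa to orient")
  if (length(net$vertices) == 2L) {
    stop("the single-edge network has no internal vertex to serve as root")
  }
  if (is.null(st)) {
    st <- find_support_tree(net)
    if (is.null(st)) stop("network is not tree-based; no orientation exists")
  }
  if (!is_support_tree(net, st)) stop("'st' is not a support tree of the network")
  tm <- if (inherits(st, "support_tree")) st$edges else canonical_edges(st)

  # adjacency of the support tree
  adj <- lapply(stats::setNames(vector("list", length(net$vertices)), net$vertices),
                function(z) character(0))
  for (i in seq_len(nrow(tm))) {
    adj[[tm[i, 1L]]] <- c(adj[[tm[i, 1L]]], tm[i, 2L])
    adj[[tm[i, 2L]]] <- c(adj[[tm[i, 2L]]], tm[i, 1L])
  }
  # BFS from x, sorted tie-break: a topological order of the tree rooted at x
  order_ <- character(0)
  queue <- x
  seen <- stats::setNames(logical(length(net$vertices)), net$vertices)
  seen[x] <- TRUE
  tree_arcs <- empty_edge_matrix()
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    order_ <- c(order_, v)
    for (w in sort(adj[[v]])) {
      if (!seen[w]) {
        seen[w] <- TRUE
        tree_arcs <- rbind(tree_arcs, c(v, w))
        queue <- c(queue, w)
      }
    }
  }
  # non-tree edges: direct away from the earlier vertex in the order
  non_tree <- edges_minus(net$edges, tm)
  oriented <- tree_arcs
  done <- character(0)
  for (v in order_) {
    touch <- which(non_tree[, 1L] == v | non_tree[, 2L] == v)
    others <- ifelse(non_tree[touch, 1L] == v, non_tree[touch, 2L],
                     non_tree[touch, 1L])
    for (w in others[order(others)]) {
      k <- edge_key(v, w)
      if (k %in% done) next
      done <- c(done, k)
      oriented <- rbind(oriented, c(v, w))
    }
  }
  orientation <- oriented[order(oriented[, 1L], oriented[, 2L]), , drop = FALSE]
  keep <- !(orientation[, 1L] == x | orientation[, 2L] == x)
  rooted <- rootednet(orientation[keep, , drop = FALSE])
  if (!identical(rooted$root, leaf_neighbour(net, x))) {
    stop("internal error: root is not the former neighbour of '", x, "'")
  }
  list(orientation = orientation, rooted = rooted)
}

#' Is a rooted network tree-based?
#'
#' A rooted network is tree-based if it contains a spanning arborescence
#' rooted at the root whose sinks are exactly the leaves.  Every non-root
#' vertex of the arborescence keeps exactly one incoming arc, so the search
#' is exact over the per-reticulation choice of incoming arc (2^r
#' assignments); an assignment succeeds when no internal vertex is stranded
#' without an outgoing arc.
#'
#' @param m a `rootednet` object
#' @param budget maximum number of reticulation assignments to try before
#'   raising a `tbnet_budget_error`
#' @param witness return the arborescence arc matrix instead of `TRUE`
#' @return logical, or (with `witness = TRUE`) an arc matrix or `NULL`
#' @export
is_rooted_tree_based <- function(m, budget = Inf, witness = FALSE) {
  stopifnot(is_rootednet(m))
  ret <- reticulations(m)
  in_arcs <- lapply(ret, function(v) which(m$arcs[, 2L] == v))
  fixed <- which(!(m$arcs[, 2L] %in% ret))        # unique in-arc: always kept
  need_out <- setdiff(m$vertices, m$leaves)       # sinks must be leaves only
  r <- length(ret)
  tries <- 0L
  choice <- integer(r)
  search <- function(k, kept) {
    if (k > r) {
      tries <<- tries + 1L
      if (tries > budget) budget_error()
      arcs <- m$arcs[sort(kept), , drop = FALSE]
      if (all(need_out %in% arcs[, 1L])) return(arcs)
      return(NULL)
    }
    for (a in in_arcs[[k]]) {
      res <- search(k + 1L, c(kept, a))
      if (!is.null(res)) return(res)
    }
    NULL
  }
  res <- search(1L, fixed)
  if (witness) res else !is.null(res)
}

#' Forget directions and attach a leaf at the root
#'
#' Adds a new taxon as a pendant edge at the root of a rooted network and
#' forgets all arc directions.  This is the exact inverse of removing a
#' leaf and its pendant edge during [orient_from_support_tree()]: the root
#' (outdegree 2) gains a third edge and becomes an internal vertex of the
#' resulting unrooted network.  If the rooted network is tree-based, the
#' result is a tree-based unrooted network.
#'
#' @param m a `rootednet` object
#' @param x new taxon label, not already used in `m`
#' @return a `phynet` object on `leaves(m)` plus `x`
#' @export
attach_leaf_at_root <- function(m, x) {
  stopifnot(is_rootednet(m))
  if (x %in% m$vertices) stop("label '", x, "' already in use")
  phynet(rbind(m$arcs, c(m$root, x)))
}

#' Is a network universal?
#'
#' A tree-based network on `X` is universal if every phylogenetic tree on
#' `X` is one of its base-trees.  All `(2|X|-5)!!` trees are enumerated and
#' tested with [is_based_on()]; feasible for small taxon sets only.
#'
#' @param net a `phynet` object
#' @param max_taxa refuse larger taxon sets (tree count grows as a double
#'   factorial)
#' @param budget per-containment search budget
#' @return logical
#' @export
is_universal <- function(net, max_taxa = 6L, budget = Inf) {
  stopifnot(is_phynet(net))
  if (length(net$leaves) > max_taxa) {
    stop("taxon set too large for exhaustive tree enumeration")
  }
  for (tr in enumerate_phylo_trees(net$leaves)) {
    if (!is_based_on(net, tr, budget = budget)) return(FALSE)
  }
  TRUE
}

#' Randomized search for a universal network
#'
#' Draws random tree-based networks on `X` (a random tree plus
#' `extra_edges` added edges) until one is universal, up to `tries`
#' attempts.
#'
#' @param x taxon labels
#' @param extra_edges number of edges added to the random tree
#' @param tries maximum number of attempts
#' @return a universal `phynet`, or `NULL` if none was found in `tries`
#'   attempts
#' @export
search_universal_network <- function(x, extra_edges = 2L, tries = 100L) {
  for (i in seq_len(tries)) {
    cand <- random_tree_based_network(x, extra_edges = extra_edges)
    if (is_universal(cand)) return(cand)
  }
  NULL
}
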