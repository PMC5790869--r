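# Independent brute-force oracles; deliberately naive, no shared code with
# the package search paths.

# bridges by remove-one-edge-and-test-connectivity
oracle_bridges <- function(net) {
  em <- net$edges
  is_bridge <- logical(nrow(em))
  for (i in seq_len(nrow(em))) {
    rest <- em[-i, , drop = FALSE]
    g <- igraph::graph_from_edgelist(rest, directed = FALSE)
    miss <- setdiff(net$vertices, igraph::V(g)$name)
    if (length(miss) > 0L) g <- igraph::add_vertices(g, length(miss), name = miss)
    is_bridge[i] <- !igraph::is_connected(g)
  }
  em[is_bridge, , drop = FALSE]
}

# all support trees by exhaustive enumeration of edge subsets of size n-1
oracle_support_trees <- function(net) {
  verts <- net$vertices
  n <- length(verts)
  em <- net$edges
  m <- nrow(em)
  if (n == 1L) return(list(matrix(character(0), ncol = 2L)))
  e1 <- match(em[, 1L], verts)
  e2 <- match(em[, 2L], verts)
  leaf <- verts %in% net$leaves
  subsets <- utils::combn(m, n - 1L)
  out <- list()
  for (k in seq_len(ncol(subsets))) {
    idx <- subsets[, k]
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    acyclic <- TRUE
    deg <- integer(n)
    for (i in idx) {
      ru <- find(e1[i]); rv <- find(e2[i])
      if (ru == rv) { acyclic <- FALSE; break }
      parent[ru] <- rv
      deg[e1[i]] <- deg[e1[i]] + 1L
      deg[e2[i]] <- deg[e2[i]] + 1L
    }
    if (!acyclic) next
    if (any(deg == 0L)) next                       # not spanning
    if (!identical(deg == 1L, leaf)) next          # leaf set must be X
    out[[length(out) + 1L]] <- em[idx, , drop = FALSE]
  }
  out
}

oracle_tree_based <- function(net) length(oracle_support_trees(net)) > 0L

# labelled enumeration of connected cubic multigraphs with canonical-form
# dedup over all vertex permutations; feasible for n <= 4
oracle_count_cubic_multigraphs <- function(n) {
  pairs <- list()
  for (i in seq_len(n)) for (j in i:n) pairs[[length(pairs) + 1L]] <- c(i, j)
  mats <- list()
  recurse <- function(p, mult, deg) {
    if (p > length(pairs)) {
      if (all(deg == 3L)) mats[[length(mats) + 1L]] <<- mult
      return(invisible())
    }
    ij <- pairs[[p]]
    i <- ij[1L]; j <- ij[2L]
    top <- if (i == j) 1L else 3L
    for (m in 0:top) {
      d2 <- deg
      if (i == j) d2[i] <- d2[i] + 2L * m else {
        d2[i] <- d2[i] + m; d2[j] <- d2[j] + m
      }
      if (any(d2 > 3L)) next
      m2 <- mult
      m2[i, j] <- m2[j, i] <- m
      recurse(p + 1L, m2, d2)
    }
    invisible()
  }
  recurse(1L, matrix(0L, n, n), integer(n))
  connected_mult <- function(m) {
    seen <- c(1L); frontier <- c(1L)
    while (length(frontier) > 0L) {
      v <- frontier[1L]; frontier <- frontier[-1L]
      for (w in seq_len(n)) {
        if (w != v && m[v, w] > 0L && !(w %in% seen)) {
          seen <- c(seen, w); frontier <- c(frontier, w)
        }
      }
    }
    length(seen) == n
  }
  mats <- Filter(connected_mult, mats)
  perms <- permutations_oracle(seq_len(n))
  canon <- vapply(mats, function(m) {
    min(vapply(perms, function(p) paste(m[p, p], collapse = ","), character(1)))
  }, character(1))
  length(unique(canon))
}

permutations_oracle <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_oracle(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# vertices of the component of `edges` minus edge `e` not containing `v`
component_without <- function(edges, e, v) {
  a <- pmin(edges[, 1L], edges[, 2L]); b <- pmax(edges[, 1L], edges[, 2L])
  keys <- paste(a, b)
  drop <- keys == paste(min(e), max(e))
  rest <- edges[!drop, , drop = FALSE]
  g <- igraph::graph_from_edgelist(rest, directed = FALSE)
  start <- setdiff(e, v)
  comp <- igraph::components(g)
  igraph::V(g)$name[comp$membership ==
                    comp$membership[match(start, igraph::V(g)$name)]]
}

edge_key_set <- function(em) {
  if (NROW(em) == 0L) return(character(0))
  a <- pmin(em[, 1L], em[, 2L]); b <- pmax(em[, 1L], em[, 2L])
  sort(paste(a, b))
}
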