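#' Construct and validate an unrooted phylogenetic network
#'
#' An unrooted binary phylogenetic network on a taxon set `X` is a connected,
#' simple graph in which every vertex has degree 1 or 3 and whose degree-1
#' vertices are exactly the taxa.  The degenerate single-vertex graph on one
#' taxon (no edges) is a valid network.
#'
#' @param edges two-column character matrix (or data frame) of undirected
#'   edges, one row per edge.  `NULL` only for the single-vertex network.
#' @param vertices optional character vector of vertex labels; needed only for
#'   the single-vertex network, otherwise inferred from `edges`.
#' @param leaves optional character vector of declared taxa.  If given, it is
#'   checked against the set of degree-1 vertices and an error is raised on
#'   mismatch.
#' @return An object of class `"phynet"`: a list with components `vertices`
#'   (sorted labels), `edges` (two-column character matrix, each row sorted,
#'   rows in lexicographic order) and `leaves` (sorted taxon labels).
#' @examples
#' quartet <- phynet(rbind(
#'   c("a", "u"), c("b", "u"), c("u", "v"), c("c", "v"), c("d", "v")))
#' leaves(quartet)
#' @export
phynet <- function(edges = NULL, vertices = NULL, leaves = NULL) {
  if (is.null(edges) || NROW(edges) == 0L) {
    if (is.null(vertices) || length(vertices) != 1L) {
      stop("a network without edges must be a single vertex (one taxon)")
    }
    net <- structure(
      list(vertices = as.character(vertices),
           edges = empty_edge_matrix(),
           leaves = as.character(vertices)),
      class = "phynet")
    check_declared_leaves(net, leaves)
    return(net)
  }
  em <- canonical_edges(edges)
  if (any(em[, 1L] == em[, 2L])) stop("loops are not allowed in a network")
  if (anyDuplicated(edge_keys(em))) stop("parallel edges are not allowed in a network")
  verts <- sort(unique(as.vector(em)))
  if (!is.null(vertices) && !setequal(vertices, verts)) {
    stop("isolated vertices are not allowed in a network with edges")
  }
  deg <- vertex_degrees(verts, em)
  bad <- verts[!(deg %in% c(1L, 3L))]
  if (length(bad) > 0L) {
    stop("every vertex must have degree 1 or 3; offending: ",
         paste(bad, " (degree ", deg[match(bad, verts)], ")", sep = "", collapse = ", "))
  }
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  if (!igraph::is_connected(g)) stop("network must be connected")
  lv <- verts[deg == 1L]
  if (length(lv) == 0L) stop("network must have at least one leaf")
  net <- structure(list(vertices = verts, edges = em, leaves = lv),
                   class = "phynet")
  check_declared_leaves(net, leaves)
  net
}

check_declared_leaves <- function(net, leaves) {
  if (!is.null(leaves) && !setequal(leaves, net$leaves)) {
    stop("declared leaves do not match the degree-1 vertices of the graph")
  }
  invisible(net)
}

#' @rdname phynet
#' @param x object to test or print
#' @export
is_phynet <- function(x) inherits(x, "phynet")

#' @export
print.phynet <- function(x, ...) {
  nl <- length(x$leaves)
  cat(sprintf("Unrooted phylogenetic network: %d vertices, %d edges, %d %s\n",
              length(x$vertices), nrow(x$edges), nl,
              if (nl == 1L) "leaf" else "leaves"))
  cat("Leaves:", paste(x$leaves, collapse = ", "), "\n")
  if (is_phynet_tree(x)) cat("The network is a tree.\n")
  invisible(x)
}

#' Leaf set of a network, tree or rooted network
#' @param x a `phynet`, `support_tree` or `rootednet` object
#' @return character vector of taxon labels
#' @export
leaves <- function(x) x$leaves

#' Is a network a phylogenetic tree?
#'
#' A phylogenetic tree is a network whose underlying graph is acyclic:
#' a single vertex (one taxon), a single edge (two taxa), or a binary
#' unrooted tree with `|X| - 2` internal vertices.
#'
#' @param net a `phynet` object
#' @return logical
#' @export
is_phynet_tree <- function(net) {
  stopifnot(is_phynet(net))
  nrow(net$edges) == length(net$vertices) - 1L
}

## ---- low-level edge helpers (shared across the package) ----

empty_edge_matrix <- function() {
  matrix(character(0), ncol = 2L, dimnames = NULL)
}

# order each row, then sort rows lexicographically; deterministic everywhere
canonical_edges <- function(edges) {
  em <- as.matrix(edges)
  if (NROW(em) == 0L) return(empty_edge_matrix())
  storage.mode(em) <- "character"
  dimnames(em) <- NULL
  if (ncol(em) != 2L) stop("edges must have two columns")
  swap <- em[, 1L] > em[, 2L]
  tmp <- em[swap, 1L]
  em[swap, 1L] <- em[swap, 2L]
  em[swap, 2L] <- tmp
  em[order(em[, 1L], em[, 2L]), , drop = FALSE]
}

edge_keys <- function(em) {
  if (NROW(em) == 0L) return(character(0))
  paste(em[, 1L], em[, 2L], sep = "\r")
}

edge_key <- function(u, v) {
  if (u > v) paste(v, u, sep = "\r") else paste(u, v, sep = "\r")
}

vertex_degrees <- function(verts, em) {
  tab <- table(factor(as.vector(em), levels = verts))
  as.integer(tab)
}

as_igraph_phynet <- function(net) {
  if (nrow(net$edges) == 0L) {
    g <- igraph::make_empty_graph(n = 1L, directed = FALSE)
    igraph::V(g)$name <- net$vertices
    return(g)
  }
  igraph::graph_from_edgelist(net$edges, directed = FALSE)
}

# subset of rows of `em` whose key is in `keys`
edges_in <- function(em, keys) {
  em[edge_keys(em) %in% keys, , drop = FALSE]
}

# set difference of edge matrices
edges_minus <- function(em, remove) {
  em[!(edge_keys(em) %in% edge_keys(canonical_edges(remove))), , drop = FALSE]
}

#' Leaf-label-preserving isomorphism of networks
#'
#' Tests whether two networks are isomorphic as leaf-labelled graphs: leaves
#' must map to the leaf with the same label, internal vertices are unlabelled.
#' With `fix_leaves = FALSE` all vertices are interchangeable (plain graph
#' isomorphism).
#'
#' @param a,b `phynet` objects (or any object with `vertices`, `edges`,
#'   `leaves` components, e.g. trees returned by [enumerate_phylo_trees()])
#' @param fix_leaves keep leaf labels fixed (default `TRUE`)
#' @return logical
#' @export
phynet_isomorphic <- function(a, b, fix_leaves = TRUE) {
  if (length(a$vertices) != length(b$vertices) ||
      nrow(a$edges) != nrow(b$edges)) return(FALSE)
  if (fix_leaves && !setequal(a$leaves, b$leaves)) return(FALSE)
  if (nrow(a$edges) == 0L) {
    return(!fix_leaves || identical(a$leaves, b$leaves))
  }
  ga <- as_igraph_phynet(a)
  gb <- as_igraph_phynet(b)
  if (fix_leaves) {
    labs <- sort(unique(c(a$leaves, b$leaves)))
    col_a <- ifelse(igraph::V(ga)$name %in% a$leaves,
                    match(igraph::V(ga)$name, labs), 0L)
    col_b <- ifelse(igraph::V(gb)$name %in% b$leaves,
                    match(igraph::V(gb)$name, labs), 0L)
    igraph::isomorphic(ga, gb, method = "vf2",
                       vertex.color1 = col_a, vertex.color2 = col_b)
  } else {
    igraph::isomorphic(ga, gb, method = "vf2")
  }
}
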