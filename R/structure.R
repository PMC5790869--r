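#' Cut-edges (bridges) of a network
#'
#' A cut-edge is an edge whose removal disconnects the network.  In a
#' phylogenetic tree every edge is a cut-edge; in a network the pendant edges
#' are always cut-edges.
#'
#' @param net a `phynet` object
#' @return two-column character matrix of cut-edges, rows sorted
#' @export
cut_edges <- function(net) {
  stopifnot(is_phynet(net))
  if (nrow(net$edges) == 0L) return(empty_edge_matrix())
  g <- as_igraph_phynet(net)
  br <- igraph::bridges(g)
  if (length(br) == 0L) return(empty_edge_matrix())
  em <- igraph::as_edgelist(igraph::subgraph_from_edges(g, br, delete.vertices = TRUE))
  canonical_edges(em)
}

is_cut_edge <- function(net, e) {
  edge_key(e[1L], e[2L]) %in% edge_keys(cut_edges(net))
}

# components of net after deleting edge e; list of two character vectors
components_after_deletion <- function(net, e) {
  em <- edges_minus(net$edges, rbind(e))
  g <- igraph::graph_from_edgelist(if (nrow(em)) em else
    matrix(net$vertices[1L], 1L, 2L), directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(net$vertices, igraph::V(g)$name)),
                            name = setdiff(net$vertices, igraph::V(g)$name))
  comp <- igraph::components(g)
  split(igraph::V(g)$name, comp$membership)
}

#' Is a cut-edge trivial?
#'
#' A cut-edge is trivial if one of the two components created by deleting it
#' is a single vertex (necessarily a leaf).
#'
#' @param net a `phynet` object
#' @param e a length-2 character vector, an edge of `net`
#' @return logical
#' @export
is_trivial_cut_edge <- function(net, e) {
  stopifnot(is_phynet(net))
  e <- as.character(e)
  if (!is_cut_edge(net, e)) stop("edge is not a cut-edge of the network")
  any(e %in% net$leaves)
}

#' Split of the taxon set induced by a cut-edge
#'
#' Deleting a cut-edge partitions the vertices into two components; the taxa
#' on either side form a split of `X` when both sides contain at least one
#' taxon.  When one side is leafless, no split is induced and `NULL` is
#' returned (such networks are not proper).
#'
#' @inheritParams is_trivial_cut_edge
#' @return a list of class `"phynet_split"` with sorted components `side_a`
#'   and `side_b` (ordered so `side_a` contains the smallest taxon), or
#'   `NULL` if one side contains no taxon
#' @export
induced_split <- function(net, e) {
  stopifnot(is_phynet(net))
  e <- as.character(e)
  if (!is_cut_edge(net, e)) stop("edge is not a cut-edge of the network")
  comps <- components_after_deletion(net, e)
  a <- sort(intersect(comps[[1L]], net$leaves))
  b <- sort(intersect(comps[[2L]], net$leaves))
  if (length(a) == 0L || length(b) == 0L) return(NULL)
  if (b[1L] < a[1L]) { tmp <- a; a <- b; b <- tmp }
  structure(list(side_a = a, side_b = b), class = "phynet_split")
}

#' @export
print.phynet_split <- function(x, ...) {
  cat(paste(x$side_a, collapse = ","), "|", paste(x$side_b, collapse = ","), "\n")
  invisible(x)
}

#' Is a network proper?
#'
#' A network is proper if every cut-edge induces a split of the taxon set,
#' i.e. no cut-edge has a leafless side.  All tree-based networks are proper.
#'
#' @param net a `phynet` object
#' @return logical
#' @export
is_proper <- function(net) {
  stopifnot(is_phynet(net))
  ce <- cut_edges(net)
  for (i in seq_len(nrow(ce))) {
    if (is.null(induced_split(net, ce[i, ]))) return(FALSE)
  }
  TRUE
}

#' Blob decomposition of a network
#'
#' A blob is a maximal subgraph without a cut-edge that is not a single
#' vertex: the non-singleton 2-edge-connected components.  A tree has no
#' blobs.
#'
#' @param net a `phynet` object
#' @return list of objects of class `"blob"`, each with components
#'   `vertices`, `edges` (edges of `net` inside the blob) and `attachments`
#'   (cut-edges of `net` with exactly one endpoint in the blob); the list is
#'   ordered by smallest vertex label
#' @export
blobs <- function(net) {
  stopifnot(is_phynet(net))
  ce <- cut_edges(net)
  non_bridge <- edges_minus(net$edges, ce)
  if (nrow(non_bridge) == 0L) return(list())
  g <- igraph::graph_from_edgelist(non_bridge, directed = FALSE)
  comp <- igraph::components(g)
  out <- list()
  for (k in seq_len(comp$no)) {
    vs <- sort(igraph::V(g)$name[comp$membership == k])
    if (length(vs) < 2L) next
    inside <- net$edges[net$edges[, 1L] %in% vs & net$edges[, 2L] %in% vs, ,
                        drop = FALSE]
    att <- net$edges[xor(net$edges[, 1L] %in% vs, net$edges[, 2L] %in% vs), ,
                     drop = FALSE]
    out[[length(out) + 1L]] <- structure(
      list(vertices = vs, edges = canonical_edges(inside),
           attachments = canonical_edges(att)),
      class = "blob")
  }
  out[order(vapply(out, function(b) b$vertices[1L], character(1)))]
}

#' @export
print.blob <- function(x, ...) {
  cat(sprintf("Blob: %d vertices, %d edges, %d attachment cut-edge(s)\n",
              length(x$vertices), nrow(x$edges), nrow(x$attachments)))
  invisible(x)
}

#' Simple network induced by a blob
#'
#' `B_N` is the union of a blob `B` and the cut-edges of the network incident
#' with it; its leaves are the outer endpoints of those cut-edges.  `B_N` is
#' always a simple network, and in a proper network it has at least two
#' leaves.
#'
#' @param net a `phynet` object
#' @param blob a blob of `net`, as returned by [blobs()]
#' @return a `phynet` object
#' @export
blob_network <- function(net, blob) {
  stopifnot(is_phynet(net), inherits(blob, "blob"))
  phynet(rbind(blob$edges, blob$attachments))
}

#' Is a network simple?
#'
#' A simple network is one all of whose cut-edges are trivial, so its
#' non-pendant part is 2-edge-connected.  Trees on more than 3 leaves are not
#' simple networks; the 3-leaf star is.
#'
#' @param net a `phynet` object
#' @return logical
#' @export
is_simple_network <- function(net) {
  stopifnot(is_phynet(net))
  ce <- cut_edges(net)
  for (i in seq_len(nrow(ce))) {
    if (!is_trivial_cut_edge(net, ce[i, ])) return(FALSE)
  }
  TRUE
}

#' Level of a network
#'
#' A network is level-k if at most k edges must be removed from each blob to
#' obtain a tree; the strict level is the maximum cycle rank
#' `|E(B)| - |V(B)| + 1` over blobs (0 for a tree).  `is_level()` uses the
#' at-most semantics: a level-1 network is also level-2.
#'
#' @param net a `phynet` object
#' @param k non-negative integer
#' @return `strict_level()`: a non-negative integer; `is_level()`: logical
#' @export
strict_level <- function(net) {
  bl <- blobs(net)
  if (length(bl) == 0L) return(0L)
  max(vapply(bl, function(b) nrow(b$edges) - length(b$vertices) + 1L, integer(1)))
}

#' @rdname strict_level
#' @export
is_level <- function(net, k) {
  stopifnot(k >= 0)
  strict_level(net) <= k
}

#' Delete a leaf from a network
#'
#' Removes taxon `x` and its pendant edge and suppresses the resulting
#' degree-2 vertex.  When suppression would create a parallel edge the result
#' is not a valid network; a flagged degenerate result (class
#' `"phynet_degenerate"`) is returned instead so callers never silently work
#' with a multigraph.
#'
#' @param net a `phynet` object with at least two taxa
#' @param x a leaf label
#' @return a `phynet`, or a `phynet_degenerate` object (test with
#'   [is_degenerate()])
#' @export
delete_leaf <- function(net, x) {
  stopifnot(is_phynet(net))
  if (!(x %in% net$leaves)) stop("'", x, "' is not a leaf of the network")
  if (length(net$leaves) < 2L) stop("cannot delete the only leaf of a network")
  nb <- leaf_neighbour(net, x)
  em <- edges_minus(net$edges, rbind(c(x, nb)))
  if (length(net$vertices) == 2L) {
    # single edge {x, y}: the survivor is the single-vertex network
    return(phynet(vertices = nb))
  }
  other <- setdiff(as.vector(em[em[, 1L] == nb | em[, 2L] == nb, , drop = FALSE]), nb)
  em <- em[!(em[, 1L] == nb | em[, 2L] == nb), , drop = FALSE]
  if (edge_key(other[1L], other[2L]) %in% edge_keys(em)) {
    return(structure(
      list(edges = rbind(em, sort(other)), parallel = sort(other),
           reason = sprintf(
             "suppressing '%s' creates a parallel edge between '%s' and '%s'",
             nb, other[1L], other[2L])),
      class = "phynet_degenerate"))
  }
  phynet(rbind(em, other))
}

#' @rdname delete_leaf
#' @param x object to test
#' @export
is_degenerate <- function(x) inherits(x, "phynet_degenerate")

#' @export
print.phynet_degenerate <- function(x, ...) {
  cat("Degenerate leaf-deletion result:", x$reason, "\n")
  invisible(x)
}

leaf_neighbour <- function(net, x) {
  em <- net$edges
  setdiff(as.vector(em[em[, 1L] == x | em[, 2L] == x, , drop = FALSE]), x)
}

#' Attach a new leaf on an edge
#'
#' Subdivides edge `e` with a new internal vertex and attaches a new pendant
#' leaf to it; the inverse of [delete_leaf()] for non-degenerate deletions.
#'
#' @param net a `phynet` object
#' @param e edge of `net` (length-2 character vector)
#' @param label new taxon label (must be fresh)
#' @param internal optional label for the subdivision vertex
#' @return a `phynet` object
#' @export
add_leaf_on_edge <- function(net, e, label, internal = NULL) {
  stopifnot(is_phynet(net))
  e <- as.character(e)
  if (!(edge_key(e[1L], e[2L]) %in% edge_keys(net$edges))) {
    stop("not an edge of the network")
  }
  if (label %in% net$vertices) stop("label '", label, "' already in use")
  if (is.null(internal)) internal <- fresh_labels(net$vertices, 1L)
  em <- edges_minus(net$edges, rbind(e))
  phynet(rbind(em, c(e[1L], internal), c(internal, e[2L]), c(internal, label)))
}

# deterministic fresh internal labels avoiding `used`
fresh_labels <- function(used, k, prefix = "v") {
  out <- character(0)
  i <- 1L
  while (length(out) < k) {
    cand <- paste0(prefix, i)
    if (!(cand %in% used)) out <- c(out, cand)
    i <- i + 1L
  }
  out
}
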