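## File formats.
##
## ".unet": one undirected edge per line as two whitespace-separated vertex
## labels; blank lines and '#' comments ignored; the single-vertex network
## is encoded as "vertex <label>".  The writer emits sorted edges, so
## write/read round-trips are byte-stable.
##
## GraphML goes through igraph; a boolean vertex attribute "is_leaf" is
## written and, when present on read, verified against the degrees.
##
## Rooted networks: one arc per line as "u -> v"; the root is inferred as
## the unique indegree-0 vertex.

#' Read and write networks in the plain edge-list format
#'
#' @param path file path
#' @param net a `phynet` object
#' @return `read_unet()`: a validated `phynet`; `write_unet()`: `path`,
#'   invisibly
#' @export
read_unet <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no edges found in '", path, "'")
  fields <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(fields) != 2L)) stop("each line must have exactly two fields")
  fm <- do.call(rbind, fields)
  if (all(fm[, 1L] == "vertex")) {
    if (nrow(fm) != 1L) stop("'vertex' lines allowed only for a single-vertex network")
    return(phynet(vertices = fm[1L, 2L]))
  }
  if (any(fm[, 1L] == "vertex")) stop("'vertex' lines allowed only for a single-vertex network")
  phynet(fm)
}

#' @rdname read_unet
#' @export
write_unet <- function(net, path) {
  stopifnot(is_phynet(net))
  if (nrow(net$edges) == 0L) {
    writeLines(paste("vertex", net$vertices), path)
  } else {
    writeLines(paste(net$edges[, 1L], net$edges[, 2L]), path)
  }
  invisible(path)
}

#' Read and write networks as GraphML
#'
#' @inheritParams read_unet
#' @return `read_graphml_net()`: a validated `phynet`;
#'   `write_graphml_net()`: `path`, invisibly
#' @export
read_graphml_net <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::vcount(g) == 1L && igraph::ecount(g) == 0L) {
    net <- phynet(vertices = igraph::V(g)$name)
  } else {
    net <- phynet(igraph::as_edgelist(g))
  }
  attrs <- igraph::vertex_attr_names(g)
  if ("is_leaf" %in% attrs) {
    declared <- igraph::V(g)$name[as.logical(igraph::V(g)$is_leaf)]
    check_declared_leaves(net, declared)
  }
  net
}

#' @rdname read_graphml_net
#' @export
write_graphml_net <- function(net, path) {
  stopifnot(is_phynet(net))
  g <- as_igraph_phynet(net)
  igraph::V(g)$is_leaf <- igraph::V(g)$name %in% net$leaves
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read and write rooted networks as directed edge lists
#'
#' One arc per line, `u -> v`; the root is inferred as the unique vertex of
#' indegree 0.
#'
#' @param path file path
#' @param m a `rootednet` object
#' @return `read_rooted()`: a validated `rootednet`; `write_rooted()`:
#'   `path`, invisibly
#' @export
read_rooted <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "[[:space:]]*->[[:space:]]*")
  if (any(lengths(fields) != 2L)) stop("each line must be of the form 'u -> v'")
  rootednet(do.call(rbind, fields))
}

#' @rdname read_rooted
#' @export
write_rooted <- function(m, path) {
  stopifnot(is_rootednet(m))
  writeLines(paste(m$arcs[, 1L], "->", m$arcs[, 2L]), path)
  invisible(path)
}

#' Write an orientation table
#'
#' Serializes an orientation (as returned by [orient_from_support_tree()])
#' as one directed edge per line, `u -> v`, covering every edge of the
#' original unrooted network.
#'
#' @param orientation two-column matrix of arcs
#' @param path file path
#' @return `path`, invisibly
#' @export
write_orientation <- function(orientation, path) {
  writeLines(paste(orientation[, 1L], "->", orientation[, 2L]), path)
  invisible(path)
}

#' Convert between trees and ape's `phylo` objects / Newick
#'
#' Phylogenetic trees (acyclic `phynet` objects) convert to and from
#' [ape::phylo] objects, and hence Newick.  Unrooted trees are written
#' rooted at an internal vertex adjacent to the lexicographically smallest
#' leaf (the usual trifurcating convention); the degenerate one- and
#' two-taxon trees are written as `a;` and `(a,b);`.
#'
#' @param net a `phynet` that is a tree
#' @param phy an [ape::phylo] object
#' @param text a Newick string
#' @param path file path
#' @return `as_phylo()`: an `ape::phylo`; `as_phynet_tree()` /
#'   `read_newick_tree()`: a `phynet`; `write_newick_tree()`: the Newick
#'   string, invisibly
#' @export
as_phylo <- function(net) {
  stopifnot(is_phynet(net), is_phynet_tree(net))
  nx <- length(net$leaves)
  if (nx < 3L) stop("ape::phylo requires at least 3 taxa; use write_newick_tree()")
  root <- leaf_neighbour(net, net$leaves[1L])
  internal <- setdiff(net$vertices, net$leaves)
  internal <- c(root, sort(setdiff(internal, root)))
  idx <- stats::setNames(seq_along(c(net$leaves, internal)),
                         c(net$leaves, internal))
  # orient edges away from the root by BFS
  adj <- adjacency_list(net$vertices, net$edges)
  edge <- matrix(0L, nrow = nrow(net$edges), ncol = 2L)
  k <- 0L
  queue <- root
  seen <- stats::setNames(logical(length(net$vertices)), net$vertices)
  seen[root] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        k <- k + 1L
        edge[k, ] <- c(idx[[v]], idx[[w]])
        queue <- c(queue, w)
      }
    }
  }
  phy <- list(edge = edge, tip.label = net$leaves, Nnode = length(internal),
              node.label = NULL)
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  ape::collapse.singles(phy)
}

#' @rdname as_phylo
#' @export
as_phynet_tree <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  phy <- ape::unroot(phy)
  labs <- c(phy$tip.label, paste0("i", seq_len(phy$Nnode)))
  em <- cbind(labs[phy$edge[, 1L]], labs[phy$edge[, 2L]])
  phynet(em)
}

#' @rdname as_phylo
#' @export
write_newick_tree <- function(net, path = NULL) {
  stopifnot(is_phynet(net), is_phynet_tree(net))
  nx <- length(net$leaves)
  txt <- if (nx == 1L) {
    paste0(net$leaves, ";")
  } else if (nx == 2L) {
    paste0("(", net$leaves[1L], ",", net$leaves[2L], ");")
  } else {
    ape::write.tree(as_phylo(net))
  }
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

#' @rdname as_phylo
#' @export
read_newick_tree <- function(text = NULL, path = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "")
  text <- trimws(text)
  bare <- sub(";$", "", text)
  if (!grepl("[(),]", bare)) return(phynet(vertices = bare))
  if (grepl("^\\([^(),]+,[^(),]+\\)$", bare)) {
    tips <- strsplit(sub("^\\(", "", sub("\\)$", "", bare)), ",")[[1L]]
    return(phynet(rbind(trimws(tips))))
  }
  as_phynet_tree(ape::read.tree(text = text))
}
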