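test_that("support-tree search agrees with the exhaustive spanning-tree oracle", {
  nets <- list(quartet_tree(), star3(), triangle3(), two_blob_net(),
               k4_net(), k4_single_leaf(), level2 = named_fixture("level2_unique"),
               petersen_net())
  set.seed(5)
  for (i in 1:5) {
    nets[[length(nets) + 1L]] <- random_tree_based_network(letters[1:4],
                                                          extra_edges = 2)
  }
  for (net in nets) {
    oracle <- oracle_support_trees(net)
    st <- find_support_tree(net)
    expect_identical(!is.null(st), length(oracle) > 0L)
    if (!is.null(st)) expect_true(is_support_tree(net, st))
    # full enumeration matches the oracle exactly, as sets of edge sets
    mine <- enumerate_support_trees(net)
    expect_identical(
      sort(vapply(mine, function(s) paste(edge_key_set(s$edges), collapse = ";"),
                  character(1))),
      sort(vapply(oracle, function(s) paste(edge_key_set(s), collapse = ";"),
                  character(1))))
  }
})

test_that("single-taxon networks are tree-based only as the single vertex", {
  expect_true(is_tree_based(phynet(vertices = "x")))
  expect_false(is_tree_based(k4_single_leaf()))
  expect_false(is_tree_based(k4_single_leaf(), use_shortcuts = FALSE))
})

test_that("a tree is its own unique support tree; the Petersen reduction has none", {
  q <- quartet_tree()
  sts <- enumerate_support_trees(q)
  expect_length(sts, 1L)
  expect_identical(sts[[1L]]$edges, q$edges)
  expect_length(enumerate_support_trees(petersen_net()), 0L)
  expect_false(is_tree_based(petersen_net()))
})

test_that("every support tree of a two-taxon network is an x-y path", {
  k4n <- k4_net()
  sts <- enumerate_support_trees(k4n)
  expect_gt(length(sts), 0L)
  for (st in sts) {
    deg <- table(factor(as.vector(st$edges), levels = st$vertices))
    expect_identical(sort(names(deg[deg == 1L])), c("x", "y"))
    expect_true(all(deg <= 2L))  # a tree with two leaves is a path
    expect_true(phynet_isomorphic(base_tree_of(k4n, st), phynet(rbind(c("x", "y")))))
  }
})

test_that("base-tree suppression keeps the leaf set and validates as a tree", {
  set.seed(9)
  for (i in 1:10) {
    net <- random_tree_based_network(letters[1:6], extra_edges = sample(1:3, 1))
    st <- attr(net, "support_tree")
    bt <- base_tree_of(net, st)
    expect_true(is_phynet_tree(bt))
    expect_identical(leaves(bt), leaves(net))
  }
  q <- quartet_tree()
  expect_identical(base_tree_of(q, find_support_tree(q))$edges, q$edges)
  expect_error(base_tree_of(q, q$edges[1:3, ]), "not a support tree")
})

test_that("display and base-tree containment can differ", {
  edge_xy <- phynet(rbind(c("x", "y")))
  pn <- petersen_net()
  # the x-y path of length 3 displays the single-edge tree ...
  expect_true(displays(pn, edge_xy))
  # ... but it is not a support tree: the Petersen graph is not Hamiltonian
  expect_false(is_based_on(pn, edge_xy))
  # K4 has a Hamiltonian cycle through every edge
  expect_true(is_based_on(k4_net(), edge_xy))
  expect_true(displays(k4_net(), edge_xy))
  # a tree is based on (and displays) exactly itself
  q <- quartet_tree()
  for (tr in enumerate_phylo_trees(letters[1:4])) {
    expect_identical(is_based_on(q, tr), phynet_isomorphic(tr, q))
    expect_identical(displays(q, tr), phynet_isomorphic(tr, q))
  }
  expect_error(is_based_on(pn, quartet_tree()), "taxon set")
})

test_that("fully tree-based characterization agrees with the subtree verifier", {
  nets <- list(quartet_tree(), star3(), triangle3(), two_blob_net(),
               k4_net(), k4_single_leaf(), named_fixture("level2_unique"),
               petersen_net(), phynet(vertices = "z"))
  set.seed(21)
  for (i in 1:5) {
    nets[[length(nets) + 1L]] <- random_tree_based_network(letters[1:4],
                                                          extra_edges = sample(0:2, 1))
  }
  for (net in nets) {
    expect_identical(is_fully_tree_based(net), fully_tree_based_direct(net),
                     info = paste(length(net$vertices), "vertices"))
  }
  # witness for the k4 network: the x-y path subtree does not span
  expect_false(is_fully_tree_based(k4_net()))
  expect_true(is_fully_tree_based(triangle3()))
})

test_that("edge-swap property holds on base-trees of simple tree-based networks", {
  # simple level-2 networks on 5 taxa give base-trees with adjacent
  # internal edges; for any two incident non-pendant base-tree edges e, e'
  # at v there is a network edge joining the subtrees beyond e and e'.
  # The subtrees are taken in the support tree (pre-suppression): the
  # component left after deleting the support-tree path that realizes the
  # base-tree edge, on the side away from v.
  far_component <- function(st_edges, from, to) {
    g <- igraph::graph_from_edgelist(st_edges, directed = FALSE)
    pth <- igraph::shortest_paths(g, from = to, to = from, output = "epath")
    g2 <- igraph::delete_edges(g, pth$epath[[1L]])
    comp <- igraph::components(g2)
    igraph::V(g2)$name[comp$membership ==
                       comp$membership[match(from, igraph::V(g2)$name)]]
  }
  gens <- enumerate_cubic_multigraphs(2L)
  nets <- unlist(lapply(gens, networks_from_generator, leaves = letters[1:5]),
                 recursive = FALSE)
  expect_gt(length(nets), 0L)
  checked <- 0L
  for (net in nets[seq_len(min(6L, length(nets)))]) {
    expect_true(is_simple_network(net))
    for (st in enumerate_support_trees(net, limit = 3L)) {
      bt <- base_tree_of(net, st)
      internal_edges <- bt$edges[!(bt$edges[, 1L] %in% leaves(bt)) &
                                 !(bt$edges[, 2L] %in% leaves(bt)), , drop = FALSE]
      if (nrow(internal_edges) < 2L) next
      for (i in seq_len(nrow(internal_edges))) {
        for (j in seq_len(nrow(internal_edges))) {
          if (i >= j) next
          shared <- intersect(internal_edges[i, ], internal_edges[j, ])
          if (length(shared) != 1L) next
          v <- shared
          far_i <- far_component(st$edges, setdiff(internal_edges[i, ], v), v)
          far_j <- far_component(st$edges, setdiff(internal_edges[j, ], v), v)
          hit <- any(net$edges[, 1L] %in% far_i & net$edges[, 2L] %in% far_j |
                     net$edges[, 1L] %in% far_j & net$edges[, 2L] %in% far_i)
          expect_true(hit)
          checked <- checked + 1L
        }
      }
    }
  }
  expect_gt(checked, 0L)
})

test_that("search budget raises a distinct undecided condition", {
  expect_error(find_support_tree(petersen_net(), budget = 3),
               class = "tbnet_budget_error")
  expect_error(fully_tree_based_direct(petersen_net(), budget = 3),
               class = "tbnet_budget_error")
})
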