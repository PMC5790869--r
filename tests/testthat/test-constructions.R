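test_that("named cubic graphs have their textbook invariants", {
  p <- petersen()
  expect_length(p$vertices, 10L)
  expect_identical(nrow(p$edges), 15L)
  g <- igraph::graph_from_edgelist(p$edges, directed = FALSE)
  expect_identical(igraph::girth(g)$girth, 5)
  k4 <- complete_graph_k4()
  expect_length(k4$vertices, 4L)
  expect_identical(nrow(k4$edges), 6L)
  k33 <- complete_bipartite_k33()
  expect_identical(nrow(k33$edges), 9L)
  expect_error(cubic_graph(rbind(c("a", "b"))), "degree 3")
})

test_that("the cubic-graph reduction produces simple two-taxon networks", {
  k4n <- cubic_to_network(complete_graph_k4())
  expect_length(k4n$vertices, 8L)
  expect_identical(strict_level(k4n), 3L)
  expect_true(is_simple_network(k4n))
  pn <- cubic_to_network(petersen())
  expect_length(pn$vertices, 14L)
  expect_identical(strict_level(pn), 6L)
  # Lemma-style count |V| = 2(|X| - 1 + k)
  expect_identical(length(pn$vertices), 2L * (2L - 1L + strict_level(pn)))
  # the construction works for every edge of the cubic graph
  for (i in c(1L, 7L, 15L)) {
    net <- cubic_to_network(petersen(), petersen()$edges[i, ])
    expect_true(is_simple_network(net))
    expect_identical(strict_level(net), 6L)
  }
})

test_that("Hamiltonicity search is exact on the named graphs", {
  expect_false(is_hamiltonian(petersen()))
  expect_true(is_hamiltonian(complete_graph_k4()))
  expect_true(is_hamiltonian(complete_bipartite_k33()))
  cyc <- hamiltonian_cycle_through(complete_graph_k4(), c("a", "b"))
  expect_length(cyc, 4L)
  expect_identical(sort(cyc), c("a", "b", "c", "d"))
  expect_identical(cyc[1L], "a")
  expect_identical(cyc[4L], "b")  # closes on the requested edge
  for (i in seq_len(15L)) {
    expect_null(hamiltonian_cycle_through(petersen(), petersen()$edges[i, ]))
  }
})

test_that("cubic multigraph enumeration matches the labelled oracle", {
  g2 <- enumerate_cubic_multigraphs(2)
  expect_length(g2, 2L)  # triple edge; single edge with a loop at each end
  expect_identical(length(enumerate_cubic_multigraphs(4)),
                   oracle_count_cubic_multigraphs(4))
  for (n in c(2L, 4L, 6L)) {
    for (g in enumerate_cubic_multigraphs(n)) {
      expect_identical(sum(g$mult) + sum(diag(g$mult)), 3L * n)  # degree sum 3n
      expect_identical(nrow(g$edges), 3L * n %/% 2L)
    }
  }
  expect_error(enumerate_cubic_multigraphs(3), "even")
  expect_error(enumerate_cubic_multigraphs(10), "up to")
})

test_that("pendant insertion yields exactly the simple networks of the generator", {
  gens2 <- enumerate_cubic_multigraphs(2)
  nets <- unlist(lapply(gens2, networks_from_generator, leaves = c("x", "y")),
                 recursive = FALSE)
  # the unique simple level-2 network on two taxa
  expect_length(nets, 1L)
  expect_identical(strict_level(nets[[1L]]), 2L)
  expect_true(is_simple_network(nets[[1L]]))
  # every output of every generator is simple with level = generator cycle rank
  for (gen in enumerate_cubic_multigraphs(4)) {
    rank <- nrow(gen$edges) - gen$n + 1L
    for (net in networks_from_generator(gen, c("x", "y"))) {
      expect_true(is_simple_network(net))
      expect_identical(strict_level(net), rank)
      expect_identical(leaves(net), c("x", "y"))
    }
  }
})

test_that("random tree-based networks carry a verified support-tree witness", {
  set.seed(123)
  for (i in 1:10) {
    extra <- sample(0:3, 1)
    net <- random_tree_based_network(letters[1:6], extra_edges = extra)
    st <- attr(net, "support_tree")
    expect_true(is_support_tree(net, st))
    expect_true(is_tree_based(net, use_shortcuts = FALSE))
    expect_length(net$vertices, 2L * 6L - 2L + 2L * extra)
  }
  # no extra edges gives a tree; fixed seed gives identical output
  t1 <- random_tree_based_network(letters[1:8], 0, seed = 99)
  expect_true(is_phynet_tree(t1))
  t2 <- random_tree_based_network(letters[1:8], 0, seed = 99)
  expect_identical(t1$edges, t2$edges)
  n1 <- random_tree_based_network(letters[1:6], 3, seed = 7)
  n2 <- random_tree_based_network(letters[1:6], 3, seed = 7)
  expect_identical(n1$edges, n2$edges)
  expect_error(random_tree_based_network(c("a", "b"), extra_edges = 1),
               "not enough")
})

test_that("tree enumeration counts follow the double factorial", {
  expect_length(enumerate_phylo_trees("a"), 1L)
  expect_length(enumerate_phylo_trees(c("a", "b")), 1L)
  expect_length(enumerate_phylo_trees(letters[1:3]), 1L)
  trees4 <- enumerate_phylo_trees(letters[1:4])
  expect_length(trees4, 3L)
  # the three quartet topologies are pairwise non-isomorphic
  for (i in 1:2) for (j in (i + 1):3) {
    expect_false(phynet_isomorphic(trees4[[i]], trees4[[j]]))
  }
  expect_length(enumerate_phylo_trees(letters[1:5]), 15L)
})

test_that("the pendant gadget splice transfers non-tree-basedness, keeping level", {
  cx <- find_level5_counterexample()
  # the counterexample itself is a strictly level-5 non-tree-based network;
  # splicing it into tree-based hosts of strict level 6 and 7 (prism
  # reductions) yields strictly level-k non-tree-based networks, k = 6, 7
  prism <- function(k) {
    o <- sprintf("o%d", seq_len(k)); i <- sprintf("i%d", seq_len(k))
    cubic_graph(rbind(cbind(o, o[c(2:k, 1L)]), cbind(i, i[c(2:k, 1L)]),
                      cbind(o, i)))
  }
  expect_identical(strict_level(cx), 5L)
  expect_false(is_tree_based(cx, use_shortcuts = FALSE))
  for (k in c(5L, 6L)) {
    host <- cubic_to_network(prism(k))
    expect_identical(strict_level(host), k + 1L)
    expect_true(is_tree_based(host, use_shortcuts = FALSE))
    spl <- replace_pendant_with_gadget(host, "x", cx)
    expect_identical(strict_level(spl), k + 1L)  # level unchanged
    expect_false(is_tree_based(spl, use_shortcuts = FALSE))
    expect_identical(sort(leaves(spl)), sort(leaves(host)))
  }
  # splicing into a lower-level host raises the level to the gadget's
  k4s <- replace_pendant_with_gadget(k4_net(), "x", cx)
  expect_identical(strict_level(k4s), 5L)
  expect_false(is_tree_based(k4s, use_shortcuts = FALSE))
  # identity gadget: the single-edge tree leaves the network unchanged
  q <- quartet_tree()
  expect_true(phynet_isomorphic(
    replace_pendant_with_gadget(q, "a", phynet(rbind(c("x", "y")))), q))
})
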