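test_that("validation-network assembly filters, caps and deduplicates", {
  # strict weight filter: an edge exactly at the minimum is dropped
  e <- tibble::tibble(node_a = c("d1", "d1"), node_b = c("GA", "GB"),
                      edge_type = "drug-gene", weight = c(0.4, 0.41))
  net <- assemble_validation_network(e, weight_min = 0.4, neighbor_cap = 40)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$node_b, "GB")

  # duplicate edge keeps the maximum weight
  e2 <- tibble::tibble(node_a = c("d1", "GA"), node_b = c("GA", "d1"),
                       edge_type = "drug-gene", weight = c(0.5, 0.7))
  e2$node_a[2] <- "d1"; e2$node_b[2] <- "GA"  # drug listed first by contract
  net2 <- assemble_validation_network(e2, weight_min = 0)
  expect_equal(nrow(net2$edges), 1L)
  expect_equal(net2$edges$weight, 0.7)

  # neighbor cap keeps the strongest edges, ties by neighbor id
  e3 <- tibble::tibble(node_a = "hub",
                       node_b = sprintf("G%02d", 1:45),
                       edge_type = "drug-gene",
                       weight = c(rep(0.9, 10), rep(0.8, 30), rep(0.5, 5)))
  net3 <- assemble_validation_network(e3, weight_min = 0.4, neighbor_cap = 40)
  expect_equal(nrow(net3$edges), 40L)
  expect_false(any(sprintf("G%02d", 41:45) %in% net3$edges$node_b))

  # gene-gene edges need both endpoints attached to the drug layer
  e4 <- tibble::tibble(
    node_a = c("d1", "GA", "GX"),
    node_b = c("GA", "GB", "GY"),
    edge_type = c("drug-gene", "gene-gene", "gene-gene"),
    weight = c(0.9, 0.8, 0.8)
  )
  net4 <- assemble_validation_network(e4, weight_min = 0.4)
  expect_false("GX" %in% net4$nodes$node)
  expect_false("GB" %in% net4$nodes$node)  # GB only reachable via gene-gene

  # raw database scores must be rescaled into [0, 1]
  e5 <- tibble::tibble(node_a = "d1", node_b = "GA",
                       edge_type = "drug-gene", weight = 700)
  expect_error(assemble_validation_network(e5), "rescale_divisor")
  net5 <- assemble_validation_network(e5, rescale_divisor = 1000)
  expect_equal(net5$edges$weight, 0.7)

  # a node cannot be both drug and gene
  e6 <- tibble::tibble(node_a = c("x", "x"), node_b = c("y", "z"),
                       edge_type = c("drug-gene", "gene-gene"),
                       weight = c(0.9, 0.9))
  expect_error(assemble_validation_network(e6), "both drug and gene")
})

test_that("degree centrality is degree over n minus one", {
  star <- tibble::tibble(node_a = "hub", node_b = sprintf("G%d", 1:4),
                         edge_type = "drug-gene", weight = 0.9)
  dc <- degree_centrality(assemble_validation_network(star, weight_min = 0))
  expect_equal(dc$degree_centrality[dc$node == "hub"], 1)
  expect_equal(dc$degree_centrality[dc$node == "G1"], 1 / 4)
})

test_that("the 57-node reference reconstruction reproduces reported centralities", {
  net <- assemble_validation_network(breast_cancer_reference_network())
  expect_equal(nrow(net$nodes), 57L)
  expect_equal(sum(net$nodes$kind == "drug"), 17L)
  dc <- degree_centrality(net)
  expect_equal(round(dc$degree_centrality[dc$node == "Camptothecin"], 3), 0.232)
  expect_equal(round(dc$degree_centrality[dc$node == "MS-275"], 3), 0.089)
  expect_equal(round(dc$degree_centrality[dc$node == "Tamoxifen"], 3), 0.661)
  expect_equal(dc$degree[dc$node == "Camptothecin"], 13L)
  expect_equal(dc$degree[dc$node == "MS-275"], 5L)
})

test_that("betweenness matches closed forms and the BFS oracle", {
  path3 <- tibble::tibble(node_a = c("a", "b"), node_b = c("b", "c"),
                          edge_type = "drug-drug", weight = 0.9)
  bt <- betweenness_centrality(assemble_validation_network(path3, weight_min = 0))
  expect_equal(bt$betweenness[bt$node == "b"], 1)
  expect_equal(bt$betweenness[bt$node %in% c("a", "c")], c(0, 0))

  cyc4 <- tibble::tibble(node_a = c("a", "b", "c", "d"),
                         node_b = c("b", "c", "d", "a"),
                         edge_type = "drug-drug", weight = 0.9)
  bt4 <- betweenness_centrality(assemble_validation_network(cyc4, weight_min = 0))
  expect_equal(bt4$betweenness, rep(0.5, 4))

  withr::with_seed(81, {
    for (i in 1:5) {
      edges <- random_validation_edges(n_drugs = 8, n_genes = 22, p_edge = 0.12,
                                       w_min = 0.45)
      net <- assemble_validation_network(edges, weight_min = 0.4)
      bt <- betweenness_centrality(net)
      nodes <- net$nodes$node
      adj <- matrix(FALSE, length(nodes), length(nodes),
                    dimnames = list(nodes, nodes))
      adj[cbind(net$edges$node_a, net$edges$node_b)] <- TRUE
      adj <- adj | t(adj)
      oracle <- betweenness_oracle(adj)
      expect_equal(bt$betweenness[match(nodes, bt$node)], oracle,
                   tolerance = 1e-9)
      # leaves mediate nothing
      leaves <- nodes[rowSums(adj) == 1]
      expect_true(all(bt$betweenness[bt$node %in% leaves] == 0))
    }
  })
})

test_that("weighted PageRank sums to one and matches dense power iteration", {
  two <- tibble::tibble(node_a = "a", node_b = "b",
                        edge_type = "drug-drug", weight = 0.9)
  pr2 <- suppressWarnings(
    pagerank_centrality(assemble_validation_network(two, weight_min = 0)))
  expect_equal(pr2$pagerank_raw, c(0.5, 0.5))

  cyc3 <- tibble::tibble(node_a = c("a", "b", "c"), node_b = c("b", "c", "a"),
                         edge_type = "drug-drug", weight = 0.8)
  w3 <- testthat::capture_warnings(
    pr3 <- pagerank_centrality(assemble_validation_network(cyc3, weight_min = 0))
  )
  expect_match(w3, "scaling undefined", all = FALSE)
  expect_equal(pr3$pagerank_raw, rep(1 / 3, 3), tolerance = 1e-10)
  expect_true(all(is.na(pr3$pagerank_scaled)))

  withr::with_seed(82, {
    edges <- random_validation_edges(n_drugs = 7, n_genes = 18, p_edge = 0.25,
                                     w_min = 0.45)
    net <- assemble_validation_network(edges, weight_min = 0.4)
    pr <- pagerank_centrality(net, damping = 0.85)
    expect_equal(sum(pr$pagerank_raw), 1, tolerance = 1e-9)
    nodes <- net$nodes$node
    w <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
    w[cbind(net$edges$node_a, net$edges$node_b)] <- net$edges$weight
    w <- pmax(w, t(w))
    oracle <- pagerank_oracle(w, damping = 0.85)
    expect_equal(pr$pagerank_raw[match(nodes, pr$node)], unname(oracle),
                 tolerance = 1e-8)
    # min-max scaling spans [0, 1]
    expect_equal(range(pr$pagerank_scaled), c(0, 1))
    # invariant under global rescaling of all edge weights
    net_half <- net
    net_half$edges$weight <- net$edges$weight / 2
    pr_half <- pagerank_centrality(net_half, damping = 0.85)
    expect_equal(pr_half$pagerank_raw, pr$pagerank_raw, tolerance = 1e-10)
  })
})

test_that("topology metrics join per node and survive relabeling", {
  withr::with_seed(83, {
    edges <- random_validation_edges(n_drugs = 6, n_genes = 10, p_edge = 0.3,
                                     w_min = 0.45)
    net <- assemble_validation_network(edges, weight_min = 0.4)
    tm <- topology_metrics(net)
    expect_named(tm, c("node", "kind", "degree", "degree_centrality",
                       "betweenness", "pagerank_raw", "pagerank_scaled"))
    expect_equal(nrow(tm), nrow(net$nodes))
    # relabel every node; metrics must follow the names
    ren <- setNames(paste0(net$nodes$node, "_x"), net$nodes$node)
    edges2 <- dplyr::mutate(net$edges,
                            node_a = unname(ren[.data$node_a]),
                            node_b = unname(ren[.data$node_b]))
    tm2 <- topology_metrics(assemble_validation_network(edges2, weight_min = 0.4))
    m <- match(paste0(tm$node, "_x"), tm2$node)
    expect_equal(tm2$degree_centrality[m], tm$degree_centrality)
    expect_equal(tm2$betweenness[m], tm$betweenness)
    expect_equal(tm2$pagerank_raw[m], tm$pagerank_raw, tolerance = 1e-9)
  })
})
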