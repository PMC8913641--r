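test_that("complete and star graphs give their closed-form attributes", {
  k4 <- complete_network(4)
  ga <- global_attributes(k4)
  expect_equal(ga$density, 1)
  expect_equal(ga$clustering_coefficient, 1)
  expect_equal(ga$network_centralization, 0)
  expect_equal(ga$heterogeneity, 0)
  expect_equal(ga$characteristic_path_length, 1)
  expect_equal(ga$shortest_paths_count, 12)
  expect_equal(ga$connected_pair_fraction, 1)
  expect_equal(ga$mean_neighbors, 3)

  star <- star_network(3)
  gs <- global_attributes(star)
  expect_equal(gs$network_centralization, 1)
  expect_equal(gs$clustering_coefficient, 0)
})

test_that("density equals mean neighbors over n - 1 on random networks", {
  for (seed in 1:20) {
    n <- 4 + (seed %% 5)
    net <- adjacency_to_network(random_adjacency(n, 0.4, seed), seed)
    ga <- global_attributes(net)
    expect_equal(ga$density, ga$mean_neighbors / (ga$n_nodes - 1),
                 tolerance = 1e-12)
    if (ga$connected_pair_fraction == 1) {
      expect_equal(ga$shortest_paths_count, ga$n_nodes * (ga$n_nodes - 1))
    }
    expect_gte(ga$heterogeneity, 0)
  }
})

test_that("heterogeneity is zero exactly for regular degree sequences", {
  expect_equal(global_attributes(ring_network(6))$heterogeneity, 0)
  expect_gt(global_attributes(star_network(4))$heterogeneity, 0)
})

test_that("isolated-node policy changes the node set consistently", {
  net <- signed_network(data.frame(source = c("a", "b"), target = c("b", "c"),
                                   r = c(0.5, 0.5)),
                        nodes = c("a", "b", "c", "iso1", "iso2"))
  ga_all <- global_attributes(net, include_isolated = TRUE)
  ga_conn <- global_attributes(net, include_isolated = FALSE)
  expect_equal(ga_all$n_nodes, 5)
  expect_equal(ga_conn$n_nodes, 3)
  expect_equal(ga_conn$density, 2 * 2 / (3 * 2))
  expect_lt(ga_all$connected_pair_fraction, 1)
  expect_equal(ga_conn$connected_pair_fraction, 1)
})

test_that("clustering average can exclude degree-<2 nodes", {
  # triangle plus a pendant: local coefficients 1, 1, 1/3 (hub), 0/NaN
  net <- signed_network(data.frame(source = c("a", "a", "b", "c"),
                                   target = c("b", "c", "c", "d")))
  z <- global_attributes(net, clustering_isolates = "zero")
  x <- global_attributes(net, clustering_isolates = "exclude")
  expect_equal(z$clustering_coefficient, (1 + 1 + 1 / 3 + 0) / 4)
  expect_equal(x$clustering_coefficient, (1 + 1 + 1 / 3) / 3)
})

test_that("path and star centralities match their textbook values", {
  path <- signed_network(data.frame(source = c("a", "b"),
                                    target = c("b", "c")))
  nc <- node_centralities(path)
  expect_equal(nc$ncc[nc$taxon == "b"], 1)
  expect_equal(nc$ncc[nc$taxon == "a"], 2 / 3)
  expect_equal(nc$nbc[nc$taxon == "b"], 1)
  expect_equal(nc$nbc[nc$taxon == "a"], 0)
  expect_equal(nc$ndc, c(1L, 2L, 1L))

  star <- star_network(5)
  ns <- node_centralities(star)
  expect_equal(ns$nbc[ns$taxon == "hub"], 1)
  expect_true(all(ns$nbc[ns$taxon != "hub"] == 0))
  expect_equal(ns$ncc[ns$taxon == "hub"], 1)
  expect_true(all(abs(ns$ncc[ns$taxon != "hub"] - 1 / mean(c(1, 2, 2, 2, 2))) < 1e-12))
})

test_that("isolated nodes get zero closeness and keep their flag", {
  net <- signed_network(data.frame(source = "a", target = "b", r = -0.7),
                        nodes = c("a", "b", "iso"))
  nc <- node_centralities(net)
  expect_equal(nc$ncc[nc$taxon == "iso"], 0)
  expect_true(nc$isolated[nc$taxon == "iso"])
  expect_equal(nc$ncc[nc$taxon == "a"], 1)
})

test_that("edge betweenness matches hand enumeration on small graphs", {
  # single edge: the one endpoint pair
  k2 <- signed_network(data.frame(source = "a", target = "b", r = 0.5))
  expect_equal(edge_betweenness_centrality(k2)$ebc, 1)

  # star with 3 leaves: each edge carries its hub pair plus two 2-hop pairs
  st <- star_network(3)
  expect_equal(edge_betweenness_centrality(st)$ebc, rep(3, 3))

  # bridge between two triangles carries all nine cross pairs
  tri2 <- signed_network(data.frame(
    source = c("a", "a", "b", "c", "d", "d", "e"),
    target = c("b", "c", "c", "d", "e", "f", "f")))
  eb <- edge_betweenness_centrality(tri2)
  bridge <- eb$ebc[edge_key(eb$source, eb$target) == "c|d"]
  expect_equal(bridge, 9)
})

test_that("centralities equal brute-force enumeration on random graphs", {
  for (seed in 1:40) {
    n <- 4 + (seed %% 5)
    adj <- random_adjacency(n, 0.35 + 0.05 * (seed %% 4), seed)
    net <- adjacency_to_network(adj, seed)
    oracle <- oracle_metrics(adj)
    nc <- node_centralities(net)
    expect_equal(nc$ndc, unname(oracle$ndc), tolerance = 1e-12)
    expect_equal(nc$ncc, unname(oracle$ncc), tolerance = 1e-12)
    expect_equal(nc$nbc, unname(oracle$nbc), tolerance = 1e-12)
    eb <- edge_betweenness_centrality(net)
    io <- match(eb$source, rownames(adj))
    jo <- match(eb$target, colnames(adj))
    expect_equal(eb$ebc,
                 oracle$ebc[cbind(pmin(io, jo), pmax(io, jo))],
                 tolerance = 1e-12)
  }
})

test_that("weighted distances are available behind the flag", {
  # two paths a-c: direct (|r| = 0.9) vs via b (0.2 + 0.2); weighted
  # shortest path prefers the low-weight detour
  net <- signed_network(data.frame(source = c("a", "b", "a"),
                                   target = c("b", "c", "c"),
                                   r = c(0.2, 0.2, 0.9)))
  nc_u <- node_centralities(net, weighted = FALSE)
  nc_w <- node_centralities(net, weighted = TRUE)
  expect_equal(nc_u$nbc[nc_u$taxon == "b"], 0) # direct edge wins on hops
  expect_equal(nc_w$nbc[nc_w$taxon == "b"], 1) # detour wins on weights
})

test_that("divisive clustering separates planted components", {
  two_tri <- signed_network(data.frame(
    source = c("a", "a", "b", "x", "x", "y"),
    target = c("b", "c", "c", "y", "z", "z")))
  cm <- network_communities(two_tri, k = 2)
  expect_equal(cm$n_communities, 2L)
  expect_equal(nrow(cm$removed_edges), 0L)
  expect_length(unique(cm$membership[c("a", "b", "c")]), 1L)
  expect_length(unique(cm$membership[c("x", "y", "z")]), 1L)
  expect_false(cm$membership[["a"]] == cm$membership[["x"]])
})

test_that("a bridge between cliques is removed first", {
  clique_edges <- function(members) {
    pr <- t(utils::combn(members, 2))
    data.frame(source = pr[, 1], target = pr[, 2], stringsAsFactors = FALSE)
  }
  edges <- rbind(clique_edges(paste0("a", 1:5)), clique_edges(paste0("b", 1:5)),
                 data.frame(source = "a1", target = "b1"))
  net <- signed_network(edges)
  cm <- network_communities(net, k = 2)
  expect_equal(nrow(cm$removed_edges), 1L)
  expect_equal(sort(unlist(cm$removed_edges[1, c("source", "target")],
                           use.names = FALSE)), c("a1", "b1"))
  expect_length(unique(cm$membership[paste0("a", 1:5)]), 1L)
})

test_that("clustering is deterministic and validates k", {
  net <- ring_network(6)
  cm1 <- network_communities(net, k = 2)
  cm2 <- network_communities(net, k = 2)
  expect_identical(cm1$membership, cm2$membership)
  expect_identical(cm1$removed_edges, cm2$removed_edges)

  expect_equal(network_communities(net, k = 1)$n_communities, 1L)
  expect_equal(nrow(network_communities(net, k = 1)$removed_edges), 0L)
  expect_error(network_communities(net, k = 7), "exceeds")
  expect_error(network_communities(
    signed_network(data.frame(), nodes = c("a", "b"))), "no edges")
})

test_that("max-modularity stop finds the obvious two-block split", {
  clique_edges <- function(members) {
    pr <- t(utils::combn(members, 2))
    data.frame(source = pr[, 1], target = pr[, 2], stringsAsFactors = FALSE)
  }
  edges <- rbind(clique_edges(paste0("a", 1:4)), clique_edges(paste0("b", 1:4)),
                 data.frame(source = "a1", target = "b1"))
  cm <- network_communities(signed_network(edges))
  expect_equal(cm$n_communities, 2L)
  expect_gt(cm$modularity, 0.3)
})

test_that("removing the top-betweenness node never reconnects the graph", {
  for (seed in 1:15) {
    adj <- random_adjacency(7, 0.3, seed + 100)
    net <- adjacency_to_network(adj, seed)
    g <- as_igraph(net)
    ga <- global_attributes(net)
    nc <- node_centralities(net)
    top <- nc$taxon[which.max(nc$nbc)]
    g2 <- igraph::delete_vertices(g, top)
    if (igraph::vcount(g2) >= 2) {
      ga2 <- global_attributes(g2)
      expect_lte(ga2$shortest_paths_count, ga$shortest_paths_count)
    }
  }
})
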