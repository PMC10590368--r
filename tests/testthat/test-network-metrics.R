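# Hand-enumerated oracles:
#   5-node star: density 0.4, centralization (5/3)(1 - 0.4) = 1,
#     clustering 0, heterogeneity sqrt(var_pop(4,1,1,1,1))/1.6 = 1.2/1.6,
#     CPL (8*1 + 12*2)/20 = 1.6, 20 ordered pairs
#   4-node path: density 0.5, centralization (4/2)(2/3 - 1/2) = 1/3,
#     CPL 20/12 = 5/3, heterogeneity 0.5/1.5 = 1/3, 12 ordered pairs
#   K5: everything at its complete-graph value

test_that("node degree counts incident edges regardless of sign", {
  net <- star5()
  expect_equal(node_degree(net, "hub"), 4L)
  expect_equal(node_degree(net, "l2"), 1L)
  expect_equal(unname(node_degree(complete_net(6))), rep(5L, 6))
  iso <- make_net(c("x", "y", "z"), cbind("x", "y"))
  expect_equal(node_degree(iso, "z"), 0L)
  expect_error(node_degree(net, "nope"), "unknown taxon")
})

test_that("local clustering matches neighbourhood enumeration", {
  tri <- make_net(c("a", "b", "c"),
                  cbind(c("a", "b", "c"), c("b", "c", "a")))
  expect_equal(local_clustering(tri, "a"), 1)
  expect_equal(local_clustering(star5(), "hub"), 0)
  expect_equal(local_clustering(star5(), "l1"), 0)
  # center x with neighbours a,b,c and a single a-b edge: 2*1/(3*2)
  g <- make_net(c("x", "a", "b", "c"),
                rbind(c("x", "a"), c("x", "b"), c("x", "c"), c("a", "b")))
  expect_equal(local_clustering(g, "x"), 1 / 3)
})

test_that("closeness is the reciprocal mean distance to reachable nodes", {
  p3 <- make_net(c("a", "b", "c"), cbind(c("a", "b"), c("b", "c")))
  expect_equal(closeness_centrality(p3, "a"), 1 / 1.5)
  expect_equal(closeness_centrality(p3, "b"), 1)
  expect_equal(unname(closeness_centrality(complete_net(5))), rep(1, 5))
  iso <- make_net(c("x", "y", "z"), cbind("x", "y"))
  expect_equal(closeness_centrality(iso, "z"), 0)
})

test_that("betweenness uses component-size normalization", {
  p3 <- make_net(c("a", "b", "c"), cbind(c("a", "b"), c("b", "c")))
  expect_equal(betweenness_centrality(p3, "b"), 1)
  expect_equal(betweenness_centrality(p3, "a"), 0)
  expect_equal(unname(betweenness_centrality(complete_net(5))), rep(0, 5))
  st <- star5()
  expect_equal(betweenness_centrality(st, "hub"), 1)
  expect_equal(betweenness_centrality(st, "l1"), 0)
})

test_that("global attributes reproduce closed-form graphs exactly", {
  k5 <- global_attributes(complete_net(5))
  expect_equal(k5$density, 1)
  expect_equal(k5$clustering_coefficient, 1)
  expect_equal(k5$network_centralization, 0)
  expect_equal(k5$characteristic_path_length, 1)
  expect_equal(k5$shortest_paths_count, 20L)
  expect_equal(k5$shortest_paths_pct, 100)
  expect_equal(k5$heterogeneity, 0)
  expect_equal(k5$avg_neighbors, 4)

  st <- global_attributes(star5())
  expect_equal(st$density, 0.4)
  expect_equal(st$network_centralization, 1)
  expect_equal(st$clustering_coefficient, 0)
  expect_equal(st$heterogeneity, 0.75)
  expect_equal(st$characteristic_path_length, 1.6)
  expect_equal(st$shortest_paths_count, 20L)

  p4 <- global_attributes(path4())
  expect_equal(p4$density, 0.5)
  expect_equal(p4$network_centralization, 1 / 3)
  expect_equal(p4$characteristic_path_length, 10 / 6)
  expect_equal(p4$heterogeneity, 1 / 3)
  expect_equal(p4$shortest_paths_count, 12L)
  expect_equal(p4$shortest_paths_pct, 100)
})

test_that("centralization separates stars from vertex-transitive graphs", {
  for (n in 5:7) {
    ring <- make_net(paste0("v", 1:n),
                     cbind(paste0("v", 1:n), paste0("v", c(2:n, 1))))
    expect_equal(global_attributes(ring)$network_centralization, 0)
    expect_equal(global_attributes(complete_net(n))$network_centralization, 0)
    nodes <- c("hub", paste0("l", seq_len(n - 1)))
    st <- make_net(nodes, cbind("hub", nodes[-1]))
    expect_equal(global_attributes(st)$network_centralization, 1)
  }
})

test_that("shortest-path coverage is 100 exactly for connected networks", {
  set.seed(5)
  for (i in 1:20) {
    A <- random_connected_adjacency(sample(4:7, 1), runif(1, 0.35, 0.8))
    expect_equal(global_attributes(net_from_adjacency(A))$shortest_paths_pct,
                 100)
  }
  two <- make_net(letters[1:4], rbind(c("a", "b"), c("c", "d")))
  expect_lt(global_attributes(two)$shortest_paths_pct, 100)
})

test_that("metrics are blind to edge signs", {
  set.seed(12)
  A <- random_connected_adjacency(7, 0.5)
  r <- runif(sum(A) / 2, 0.3, 1)
  pos <- net_from_adjacency(A, r = r)
  neg <- net_from_adjacency(A, r = -r)
  expect_equal(unclass(global_attributes(pos)),
               unclass(global_attributes(neg)))
  expect_equal(node_table(pos), node_table(neg))
})

test_that("isolated nodes are excluded from global metrics but reported", {
  g <- make_net(c("a", "b", "c", "iso"),
                rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  ga <- global_attributes(g)
  expect_equal(ga$n_nodes, 3L)
  expect_equal(ga$n_isolated_excluded, 1L)
  expect_equal(ga$density, 1)
  gi <- global_attributes(g, include_isolated = TRUE)
  expect_equal(gi$n_nodes, 4L)
  expect_equal(gi$density, 0.5)
  # node table still lists everyone
  expect_equal(nrow(node_table(g)), 4L)
})

test_that("edgeless and empty networks degrade gracefully", {
  lone <- make_net(c("a", "b", "c"), NULL)
  ga <- global_attributes(lone, include_isolated = TRUE)
  expect_true(is.na(ga$characteristic_path_length))
  expect_equal(ga$shortest_paths_count, 0L)
  expect_equal(nrow(node_table(make_net(character(0), NULL))), 0L)
})

test_that("node table ranks hubs first and breaks ties by name", {
  nt <- node_table(star5(), sort_by = "NDC")
  expect_equal(nt$taxon[1], "hub")
  expect_equal(nt$taxon[-1], sort(nt$taxon[-1]))
  k4 <- node_table(complete_net(4))
  expect_true(all(k4$NDC == 3L & k4$NCC == 1 & k4$NBC == 0 & k4$CCF == 1))
})

test_that("every metric agrees with the path-enumeration oracle", {
  set.seed(88)
  for (i in 1:60) {
    n <- sample(4:7, 1)
    A <- random_connected_adjacency(n, runif(1, 0.3, 0.9))
    net <- net_from_adjacency(A)
    ref <- bf_metrics(A)
    ga <- global_attributes(net)
    nt <- node_table(net)
    ord <- match(rownames(A), nt$taxon)
    expect_equal(nt$NDC[ord], unname(as.integer(ref$degree)))
    expect_equal(nt$NCC[ord], ref$ncc, tolerance = 1e-9)
    expect_equal(nt$NBC[ord], ref$nbc, tolerance = 1e-9)
    expect_equal(nt$CCF[ord], ref$ccf, tolerance = 1e-9)
    for (f in c("clustering_coefficient", "network_centralization",
                "characteristic_path_length", "avg_neighbors", "density",
                "heterogeneity", "shortest_paths_pct"))
      expect_equal(ga[[f]], ref[[f]], tolerance = 1e-9)
    expect_equal(ga$shortest_paths_count, as.integer(ref$shortest_paths_count))
  }
})

test_that("weighted path mode matches weighted enumeration", {
  set.seed(19)
  for (i in 1:10) {
    n <- sample(4:6, 1)
    A <- random_connected_adjacency(n, 0.6)
    net <- net_from_adjacency(A)
    W <- matrix(0, n, n)
    ed <- network_edges(net)
    ia <- match(ed$taxon_a, rownames(A))
    ib <- match(ed$taxon_b, rownames(A))
    W[cbind(ia, ib)] <- W[cbind(ib, ia)] <- ed$weight
    dref <- bf_weighted_dist(A, W)
    ncc_ref <- sapply(seq_len(n), function(v) {
      reach <- dref[v, ][is.finite(dref[v, ]) & dref[v, ] > 0]
      if (length(reach) == 0) 0 else 1 / mean(reach)
    })
    got <- closeness_centrality(net, mode = "weighted")
    expect_equal(unname(got[rownames(A)]), ncc_ref, tolerance = 1e-9)
    cpl <- global_attributes(net, mode = "weighted")$characteristic_path_length
    expect_equal(cpl, mean(dref[is.finite(dref) & dref > 0]),
                 tolerance = 1e-9)
  }
})

test_that("class comparison aligns attributes and extracts top taxa", {
  nets <- list(A = star5(), B = complete_net(5))
  cmp <- compare_classes(nets, ndc_cut = 3, nbc_cut = 0.5, ncc_cut = 0.99)
  expect_equal(colnames(cmp$attributes), c("attribute", "A", "B"))
  expect_equal(cmp$top_taxa$A$taxon, "hub")
  expect_equal(nrow(cmp$top_taxa$B), 5L)    # all NDC 4 > 3
  same <- compare_classes(list(X = star5(), Y = star5()))
  expect_equal(same$attributes$X, same$attributes$Y)
})
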