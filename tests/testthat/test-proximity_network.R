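test_that("build_network counts dyad co-scans and drops isolated individuals", {
  ros <- tiny_roster()
  scans <- rbind(scan_row("F01", 1, males_2m = "M01"),
                 scan_row("F01", 2, males_2m = "M01", males_5m = "M02"),
                 scan_row("F01", 3, males_5m = "M02"),
                 scan_row("F02", 3))
  g2 <- build_network(scans, "two_m", roster = ros)
  expect_setequal(igraph::V(g2)$name, c("F01", "M01"))
  eid <- igraph::get_edge_ids(g2, c("F01", "M01"))
  expect_equal(igraph::E(g2)$weight[eid], 2)
  # M02 only ever in the 5-m annulus: absent at 2 m, present at 5 m
  g5 <- build_network(scans, "five_m", roster = ros)
  expect_true("M02" %in% igraph::V(g5)$name)
  expect_equal(igraph::E(g5)$weight[igraph::get_edge_ids(g5, c("F01", "M02"))], 2)
  expect_equal(igraph::E(g5)$weight[igraph::get_edge_ids(g5, c("F01", "M01"))], 2)
  expect_error(build_network(scans, "two_m", window = c(90, 95)), "empty-network")
})

test_that("the 5-m relation is cumulative: edge set contains the 2-m edges", {
  set.seed(31)
  sim <- shared_sim()
  ros <- sim$truth$roster
  for (rep in 1:100) {
    idx <- sample(nrow(sim$scans), 200)
    sc <- sim$scans[idx, ]
    g2 <- tryCatch(build_network(sc, "two_m"), error = function(e) NULL)
    g5 <- build_network(sc, "five_m")
    if (is.null(g2)) next
    e2 <- apply(igraph::as_edgelist(g2), 1, function(x) paste(sort(x), collapse = "|"))
    e5 <- apply(igraph::as_edgelist(g5), 1, function(x) paste(sort(x), collapse = "|"))
    expect_true(all(e2 %in% e5))
  }
})

test_that("density and degree stats use the unweighted dyad counts", {
  g <- igraph::make_full_graph(3)
  expect_equal(net_density(g), 1.0)
  expect_error(net_density(igraph::make_empty_graph(1, directed = FALSE)),
               "undefined-metric")
  g1 <- igraph::make_graph(c(1, 2), directed = FALSE)
  ds <- degree_stats(g1)
  expect_equal(ds$mean, 1.0)
  expect_equal(ds$range, c(1, 1))
  # weighted strength reported separately from degree
  gw <- igraph::make_graph(c(1, 2, 2, 3), directed = FALSE)
  igraph::E(gw)$weight <- c(5, 7)
  dsw <- degree_stats(gw)
  expect_equal(unname(dsw$degree), c(1, 2, 1))
  expect_equal(unname(dsw$strength), c(5, 12, 7))
})

test_that("modularity: frozen small cases and the brute-force oracle", {
  two_tri <- igraph::make_graph(c(1,2, 2,3, 1,3, 4,5, 5,6, 4,6), directed = FALSE)
  expect_equal(modularity_q(two_tri, c(1, 1, 1, 2, 2, 2)), 0.5)
  expect_equal(modularity_q(two_tri, rep(1, 6)), 0)
  tri <- igraph::make_graph(c(1, 2, 2, 3, 1, 3), directed = FALSE)
  expect_equal(modularity_q(tri, 1:3), -1 / 3)
  expect_error(modularity_q(tri, c(a = 1)), "partition error")

  set.seed(77)
  for (rep in 1:50) {
    g <- random_small_graph()
    mem <- sample(1:3, igraph::vcount(g), replace = TRUE)
    expect_equal(modularity_q(g, mem), brute_modularity(graph_adjacency(g), mem),
                 tolerance = 1e-12)
  }
})

test_that("walktrap: clique pair, disconnected components, zero-edge graphs", {
  # two 4-cliques joined by a single edge; exhaustive search confirms the
  # two cliques are the best partition (frozen from best_partition_modularity)
  g <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
  g <- igraph::add_edges(g, c(1, 5))
  wt <- walktrap_partition(g)
  expect_equal(wt$n_communities, 2)
  expect_equal(unname(wt$membership[1:4]), rep(wt$membership[[1]], 4))
  expect_equal(unname(wt$membership[5:8]), rep(wt$membership[[5]], 4))
  expect_equal(wt$modularity, best_partition_modularity(g), tolerance = 1e-9)

  # disconnected: no community spans components
  gd <- igraph::make_full_graph(3) + igraph::make_full_graph(3)
  wd <- walktrap_partition(gd)
  expect_equal(wd$n_communities, 2)
  comp <- igraph::components(gd)$membership
  expect_true(all(tapply(wd$membership, comp, function(x) length(unique(x))) == 1))

  ge <- igraph::make_empty_graph(4, directed = FALSE)
  we <- walktrap_partition(ge)
  expect_equal(we$n_communities, 4)
})

test_that("potts annealer recovers exhaustive optima and honours gamma", {
  two_tri <- igraph::make_graph(c(1,2, 2,3, 1,3, 4,5, 5,6, 4,6), directed = FALSE)
  pt <- potts_partition(two_tri, seed = 2, restarts = 5)
  expect_equal(pt$modularity, 0.5)
  expect_equal(pt$n_communities, 2)
  expect_error(potts_partition(two_tri, gamma = 0), "gamma")
  # gamma -> 0 removes the null-model penalty: one community is optimal
  pt0 <- potts_partition(two_tri, gamma = 1e-6, seed = 2, restarts = 3)
  expect_equal(pt0$n_communities, 2)  # disconnected: no cross-component gain
  path <- igraph::make_ring(6)
  pt_r <- potts_partition(path, gamma = 1e-6, seed = 2, restarts = 3)
  expect_equal(pt_r$n_communities, 1)
  # reproducibility
  expect_identical(potts_partition(two_tri, seed = 9, restarts = 3)$membership,
                   potts_partition(two_tri, seed = 9, restarts = 3)$membership)
})

test_that("potts and walktrap agree on planted two-block networks", {
  set.seed(12)
  agree <- 0L
  n_rep <- 20
  for (rep in seq_len(n_rep)) {
    g <- igraph::sample_sbm(10, pref.matrix = matrix(c(0.9, 0.05, 0.05, 0.9), 2),
                            block.sizes = c(5, 5))
    if (igraph::ecount(g) == 0) next
    igraph::E(g)$weight <- 1
    wt <- walktrap_partition(g)$membership
    pt <- potts_partition(g, seed = rep, restarts = 4)$membership
    if (all(tapply(pt, wt, function(x) length(unique(x))) == 1) &&
        length(unique(pt)) == length(unique(wt))) agree <- agree + 1L
  }
  expect_gte(agree, round(0.95 * n_rep))
})

test_that("pairing success counts females co-assigned with their primary male", {
  g <- igraph::make_graph(c("F1", "M1", "F2", "M1", "F3", "M2"), directed = FALSE)
  mem <- c(F1 = 1, M1 = 1, F2 = 2, F3 = 2, M2 = 2)
  prim <- c(F1 = "M1", F2 = "M1", F3 = "M2")
  expect_equal(pairing_success(g, mem, prim), 2 / 3)
  expect_equal(pairing_success(g, stats::setNames(rep(1, 5), names(mem)), prim), 1)
  # absent primary male counts as failure, with a warning
  prim2 <- c(F1 = "M9", F2 = "M1", F3 = "M2")
  expect_warning(ps <- pairing_success(g, mem, prim2), "absent")
  expect_equal(ps, 1 / 3)  # F1's male absent, F2 not co-assigned, F3 co-assigned
})

test_that("network export formats round-trip the edge structure", {
  sim <- shared_sim()
  g <- build_network(sim$scans, "two_m", window = c(1, 56), roster = sim$truth$roster)
  dir <- withr::local_tempdir()
  write_edgelist_csv(g, file.path(dir, "e.csv"))
  el <- utils::read.csv(file.path(dir, "e.csv"))
  expect_equal(nrow(el), igraph::ecount(g))
  expect_equal(sum(el$weight), sum(igraph::E(g)$weight))
  write_graphml(g, file.path(dir, "g.graphml"))
  g2 <- igraph::read_graph(file.path(dir, "g.graphml"), format = "graphml")
  expect_equal(igraph::vcount(g2), igraph::vcount(g))
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
})
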