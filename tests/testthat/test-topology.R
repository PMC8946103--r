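triangle <- as_network(cbind(c("a", "b", "c"), c("b", "c", "a")))
star5 <- as_network(cbind("hub", paste0("l", 1:4)))
path3 <- as_network(cbind(c("A", "B"), c("B", "C")))
k4 <- as_network(t(utils::combn(letters[1:4], 2L)))

test_that("degree distribution matches hand counts and sums to one", {
  expect_equal(degree_distribution_profile(triangle)$value, 1)
  p5 <- degree_distribution_profile(star5)
  expect_equal(p5$k, c(1L, 4L))
  expect_equal(p5$value, c(0.8, 0.2))
  p3 <- degree_distribution_profile(path3)
  expect_equal(p3$value, c(2 / 3, 1 / 3))
  for (s in 1:10) {
    net <- random_net(sample(5:40, 1L), 0.3, seed = s)
    pr <- degree_distribution_profile(net)
    expect_equal(sum(pr$value), 1, tolerance = 1e-12)
    expect_equal(sum(igraph::degree(net)), 2L * network_edges(net))
  }
})

test_that("clustering profile excludes k<2 and matches the paw graph value", {
  expect_equal(clustering_by_degree(k4)$value, 1)
  s5 <- clustering_by_degree(star5)
  expect_equal(s5$k, 4L)
  expect_equal(s5$value, 0)
  paw <- as_network(rbind(c("A", "B"), c("B", "C"), c("C", "A"),
                          c("A", "D")))
  cc <- local_clustering(paw)
  expect_equal(unname(cc["A"]), 1 / 3)
  expect_equal(unname(cc["D"]), 0)
  prof <- clustering_by_degree(paw)
  expect_false(1L %in% prof$k) # pendant D excluded
})

test_that("neighborhood connectivity equals hand enumeration", {
  expect_equal(neighborhood_connectivity(k4)$value, 3)
  cn5 <- neighborhood_connectivity(star5)
  expect_equal(cn5$value, c(4, 1))
  p4 <- as_network(cbind(c("A", "B", "C"), c("B", "C", "D")))
  cn <- neighborhood_connectivity(p4)
  expect_equal(cn$value[cn$k == 1L], 2)
  expect_equal(cn$value[cn$k == 2L], 1.5)
})

test_that("closeness works per component", {
  expect_equal(unname(as.numeric(closeness_centrality(k4))), rep(1, 4))
  cc <- closeness_centrality(path3)
  expect_equal(unname(cc["B"]), 1)
  expect_equal(unname(cc["A"]), 2 / 3)
  two_edges <- as_network(rbind(c("a", "b"), c("c", "d")))
  expect_equal(unname(as.numeric(closeness_centrality(two_edges))), rep(1, 4))
})

test_that("eigenvector centrality has unit norm and known symmetry values", {
  ek4 <- eigenvector_centrality(k4)
  expect_equal(unname(as.numeric(ek4)), rep(0.5, 4), tolerance = 1e-9)
  e5 <- eigenvector_centrality(star5)
  expect_equal(unname(e5["hub"] / e5["l1"]), 2, tolerance = 1e-8)
  ee <- eigenvector_centrality(as_network(rbind(c("x", "y"))))
  expect_equal(unname(as.numeric(ee)), rep(1 / sqrt(2), 2), tolerance = 1e-10)
})

test_that("betweenness matches hand values raw and normalized", {
  bw <- betweenness_centrality(path3, normalized = FALSE)
  expect_equal(unname(bw["B"]), 1)
  expect_equal(unname(bw["A"]), 0)
  expect_equal(unname(as.numeric(betweenness_centrality(k4))), rep(0, 4))
  b5 <- betweenness_centrality(star5, normalized = FALSE)
  expect_equal(unname(b5["hub"]), 6)
  b5n <- betweenness_centrality(star5, normalized = TRUE)
  expect_equal(unname(b5n["hub"]), 1)
})

test_that("binned measures average by degree class", {
  b5 <- betweenness_centrality(star5, normalized = FALSE)
  prof <- bin_measure_by_degree(star5, b5)
  expect_equal(prof$value, c(0, 6))
  const <- node_measure(stats::setNames(rep(2.5, 4), igraph::V(k4)$name), "x")
  expect_equal(bin_measure_by_degree(k4, const)$value, 2.5)
  expect_equal(bin_measure_by_degree(
    k4, closeness_centrality(k4))$value, 1)
})

test_that("centralities agree with brute-force oracles on random graphs", {
  for (s in 1:40) {
    net <- random_net(sample(5:30, 1L), stats::runif(1, 0.1, 0.5), seed = s)
    ids <- igraph::V(net)$name
    expect_equal(as.numeric(betweenness_centrality(net, normalized = FALSE)[ids]),
                 unname(bf_betweenness(net)[ids]), tolerance = 1e-9)
    expect_equal(as.numeric(closeness_centrality(net)[ids]),
                 unname(bf_closeness(net)[ids]), tolerance = 1e-9)
    expect_equal(as.numeric(local_clustering(net)[ids]),
                 unname(bf_clustering(net)[ids]), tolerance = 1e-12)
  }
  for (s in 1:10) {
    net <- random_net(sample(10:50, 1L), 0.15, seed = 500 + s)
    ids <- igraph::V(net)$name
    expect_equal(as.numeric(eigenvector_centrality(net)[ids]),
                 unname(bf_eigen(net)[ids]), tolerance = 1e-8)
  }
})

test_that("all measures are invariant under node relabeling", {
  for (s in 1:10) {
    net <- random_net(12, 0.3, seed = 900 + s)
    perm <- sample(igraph::vcount(net))
    relabeled <- igraph::permute(net, perm)
    for (fn in list(betweenness_centrality, closeness_centrality,
                    local_clustering)) {
      a <- fn(net)
      b <- fn(relabeled)
      expect_equal(unname(a[sort(names(a))]), unname(b[sort(names(b))]),
                   tolerance = 1e-10)
    }
    pa <- degree_distribution_profile(net)
    pb <- degree_distribution_profile(relabeled)
    expect_equal(pa$value, pb$value)
  }
})
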