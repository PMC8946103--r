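two_triangles <- as_network(rbind(c("a", "b"), c("b", "c"), c("c", "a"),
                                  c("x", "y"), c("y", "z"), c("z", "x")))

test_that("louvain finds the exact optimum on two disjoint triangles", {
  lp <- louvain_partition(two_triangles, rng_seed = 1L)
  expect_equal(length(lp$communities), 2L)
  expect_equal(lp$q, 0.5)
  expect_equal(lp$q, bf_max_modularity(two_triangles))
})

test_that("a single triangle is not split", {
  tri <- as_network(rbind(c("a", "b"), c("b", "c"), c("c", "a")))
  lp <- louvain_partition(tri, rng_seed = 3L)
  expect_equal(length(lp$communities), 1L)
  expect_equal(lp$q, 0)
  expect_error(louvain_partition(as_network(matrix(character(0), ncol = 2),
                                            isolates = c("u", "v"))),
               "edgeless")
})

test_that("louvain Q is near the exhaustive maximum on small graphs", {
  for (s in 1:15) {
    net <- random_net(sample(5:8, 1L), stats::runif(1, 0.25, 0.6),
                      seed = 40 + s)
    if (igraph::ecount(net) == 0L) next
    lp <- louvain_partition(net, rng_seed = s)
    expect_gte(lp$q, bf_max_modularity(net) - 0.02)
  }
})

test_that("a ring of eight K5 cliques is resolved into its cliques", {
  blocks <- lapply(1:8, function(b) sprintf("c%d_%d", b, 1:5))
  edges <- do.call(rbind, lapply(blocks, function(b) t(utils::combn(b, 2L))))
  ring <- do.call(rbind, lapply(1:8, function(b) {
    c(blocks[[b]][1L], blocks[[b %% 8 + 1]][2L])
  }))
  net <- as_network(rbind(edges, ring))
  for (s in 1:10) {
    lp <- louvain_partition(net, rng_seed = s)
    expect_equal(length(lp$communities), 8L)
    sizes <- sort(vapply(lp$communities, length, 0L))
    expect_equal(sizes, rep(5L, 8L))
  }
})

test_that("decomposition of a single clique is a depth-0 tree", {
  k6 <- as_network(t(utils::combn(paste0("n", 1:6), 2L)))
  tree <- decompose_network(k6, hub_threshold = 1L, rng_seed = 1L)
  expect_equal(tree$max_depth, 0L)
  expect_equal(length(tree$motif_levels), 0L)
  expect_error(key_regulators(tree), "no key regulators")
})

test_that("planted hubs are traced to their motif and become key regulators", {
  gen <- planted_hub_hierarchy(rng_seed = 3L)
  tree <- decompose_network(gen$network, hub_threshold = gen$truth$hub_floor,
                            rng_seed = 1003L)
  expect_setequal(tree$hubs, gen$truth$planted_hub_ids)
  expect_setequal(motif_localized_hubs(tree), gen$truth$planted_hub_ids)
  expect_setequal(key_regulators(tree), gen$truth$planted_hub_ids)

  # trace invariants: x non-increasing, P_KR in (0, 1], partition validity
  for (h in tree$hubs) {
    tr <- tree$traces[[h]]
    expect_true(all(diff(tr$x_by_level) <= 0))
    pkr <- pkr_profile(tree, gen$network, h)
    expect_true(all(pkr$p_kr > 0 & pkr$p_kr <= 1))
  }
  check_partition <- function(node) {
    if (length(node$children) > 0L) {
      kids <- unlist(lapply(node$children, `[[`, "members"))
      expect_setequal(kids, node$members)
      expect_equal(anyDuplicated(kids), 0L)
      for (ch in node$children) check_partition(ch)
    }
    if (node$is_motif) {
      expect_equal(length(node$members), 3L)
      expect_equal(node$n_edges, 3L)
    }
  }
  check_partition(tree$root)
})

test_that("with two planted tiers only the deeper triple are key regulators", {
  gen <- planted_hub_hierarchy(motif_depths = c(2L, 4L), rng_seed = 2L)
  tree <- decompose_network(gen$network, hub_threshold = gen$truth$hub_floor,
                            rng_seed = 502L)
  shallow <- paste0("C1_H", 1:3)
  deep <- paste0("C2_H", 1:3)
  expect_setequal(motif_localized_hubs(tree), c(shallow, deep))
  expect_setequal(key_regulators(tree), deep)
  lv <- vapply(tree$traces[c(shallow[1L], deep[1L])],
               function(t) t$deepest_motif_level, 0L)
  expect_gt(lv[2L], lv[1L])
})

test_that("P_KR follows the edge-share arithmetic", {
  # gene with 10 of 100 edges at the root
  hub_edges <- cbind("g", sprintf("t%02d", 1:10))
  filler <- t(utils::combn(sprintf("f%02d", 1:14), 2L))[1:90, ]
  net <- as_network(rbind(hub_edges, filler))
  tree <- decompose_network(net, hub_threshold = 10L, rng_seed = 1L,
                            max_levels = 0L)
  pkr <- pkr_profile(tree, net, "g")
  expect_equal(pkr$p_kr[1L], 0.1)
  expect_error(pkr_profile(tree, net, "ghost"), "not in network")

  # inside a motif the share is 2 of the triangle's 3 edges
  gen <- planted_hub_hierarchy(rng_seed = 3L)
  tree2 <- decompose_network(gen$network, hub_threshold = gen$truth$hub_floor,
                             rng_seed = 1003L)
  kr <- key_regulators(tree2)[1L]
  prof <- pkr_profile(tree2, gen$network, kr)
  expect_equal(prof$p_kr[nrow(prof)], 2 / 3)
})

test_that("modularity by level averages split quality and tracks motifs", {
  gen <- planted_hub_hierarchy(rng_seed = 5L)
  tree <- decompose_network(gen$network, hub_threshold = gen$truth$hub_floor,
                            rng_seed = 1005L)
  mbl <- modularity_by_level(tree)
  expect_equal(mbl$level[1L], 0L)
  expect_true(all(mbl$n_communities >= 1L))
  expect_equal(attr(mbl, "n_motifs"), length(tree$motif_levels))
  # the root split's Q is that of louvain at the derived seed
  expect_equal(mbl$mean_q[1L], tree$root$q_of_split)
})

test_that("decomposition is deterministic under a fixed seed", {
  gen <- planted_hub_hierarchy(rng_seed = 4L)
  t1 <- decompose_network(gen$network, hub_threshold = gen$truth$hub_floor,
                          rng_seed = 77L)
  t2 <- decompose_network(gen$network, hub_threshold = gen$truth$hub_floor,
                          rng_seed = 77L)
  expect_identical(t1$traces, t2$traces)
  expect_identical(modularity_by_level(t1), modularity_by_level(t2))
})
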