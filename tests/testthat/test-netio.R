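test_that("edge-list reading deduplicates, drops self-loops and validates", {
  f <- withr::local_tempfile(lines = c("A\tB", "B\tA", "A\tA"))
  net <- suppressMessages(read_edge_list(f, delimiter = "\t"))
  expect_setequal(igraph::V(net)$name, c("A", "B"))
  expect_equal(network_edges(net), 1L)

  f2 <- withr::local_tempfile(lines = c("# comment", "A B", "B C"))
  net2 <- read_edge_list(f2)
  expect_equal(network_size(net2), 3L)
  expect_equal(network_edges(net2), 2L)

  f3 <- withr::local_tempfile(lines = c("A B", "oops"))
  expect_error(read_edge_list(f3), "malformed line 2")
  f4 <- withr::local_tempfile(lines = "# nothing here")
  expect_error(read_edge_list(f4), "no edges")
})

test_that("SIF lines expand to star edges and lone nodes become isolates", {
  f <- withr::local_tempfile(lines = c("A pp B C", "D pp E", "Z"))
  net <- read_edge_list(f, format = "sif")
  expect_setequal(igraph::V(net)$name, c("A", "B", "C", "D", "E", "Z"))
  expect_equal(network_edges(net), 3L)
  expect_equal(unname(igraph::degree(net)["Z"]), 0)
})

test_that("write/read round trip preserves node and edge sets incl. isolates", {
  net <- as_network(cbind(c("a", "b", "c"), c("b", "c", "a")),
                    isolates = "lonely")
  f <- withr::local_tempfile()
  write_edge_list(net, f)
  back <- read_edge_list(f, delimiter = "\t")
  # isolates ride along as comment lines; the reader alone recovers edges
  expect_equal(network_edges(back), 3L)
  expect_true(all(c("a", "b", "c") %in% igraph::V(back)$name))
  expect_match(paste(readLines(f), collapse = "\n"), "isolate:\tlonely")
})

test_that("annotations parse flags strictly and absent nodes lookup as NA", {
  f <- withr::local_tempfile(lines = c("node\tdrug_associated\tsource",
                                       "APP\ttrue\tdb1", "FYN\tfalse\tdb2",
                                       "TPI1\t1\tdb1"))
  ann <- read_annotations(f)
  expect_s3_class(ann, "node_annotations")
  expect_equal(unname(is_drug_associated(ann, c("APP", "FYN", "TPI1"))),
               c(TRUE, FALSE, TRUE))
  expect_true(is.na(is_drug_associated(ann, "GHOST")))
  expect_equal(ann$source, c("db1", "db2", "db1"))

  fe <- withr::local_tempfile(lines = "node\tdrug_associated")
  expect_equal(nrow(read_annotations(fe)), 0L)
  fb <- withr::local_tempfile(lines = c("id\tflag", "x\t1"))
  expect_error(read_annotations(fb), "required column")
  fv <- withr::local_tempfile(lines = c("node\tdrug_associated", "x\tmaybe"))
  expect_error(read_annotations(fv), "invalid drug_associated")
})

test_that("induced subgraphs keep exactly the qualifying edges", {
  k4 <- as_network(t(utils::combn(c("a", "b", "c", "d"), 2L)))
  tri <- induced_network(k4, c("a", "b", "c"))
  expect_equal(network_size(tri), 3L)
  expect_equal(network_edges(tri), 3L)
  expect_equal(network_edges(induced_network(k4, igraph::V(k4)$name)), 6L)

  path <- as_network(cbind(c("A", "B"), c("B", "C")))
  ends <- induced_network(path, c("A", "C"))
  expect_equal(network_edges(ends), 0L)
  expect_error(induced_network(path, character(0)), "non-empty")
  expect_error(induced_network(path, c("A", "Q")), "not in network")

  # brute-force edge count on random graphs
  for (s in 1:20) {
    net <- random_net(sample(5:50, 1L), 0.2, seed = s)
    members <- sample(igraph::V(net)$name,
                      sample(2:igraph::vcount(net), 1L))
    el <- igraph::as_edgelist(net)
    expected <- sum(el[, 1L] %in% members & el[, 2L] %in% members)
    expect_equal(network_edges(induced_network(net, members)), expected)
  }
})

test_that("node removal conserves incident-edge counts and keeps isolates", {
  s5 <- as_network(cbind("hub", paste0("leaf", 1:4)))
  cut <- suppressMessages(remove_network_nodes(s5, "hub"))
  expect_equal(network_size(cut), 4L)
  expect_equal(network_edges(cut), 0L)
  expect_equal(attr(cut, "newly_isolated"), 4L)

  expect_equal(network_edges(remove_network_nodes(s5, character(0))), 4L)
  tri <- as_network(cbind(c("a", "b", "c"), c("b", "c", "a")))
  expect_equal(network_edges(suppressMessages(remove_network_nodes(tri, "a"))), 1L)
  expect_error(remove_network_nodes(tri, c("a", "b", "c")), "empty result")

  for (s in 1:15) {
    net <- random_net(sample(6:40, 1L), 0.25, seed = 100 + s)
    victims <- sample(igraph::V(net)$name, sample(1:3, 1L))
    el <- igraph::as_edgelist(net)
    incident <- sum(el[, 1L] %in% victims | el[, 2L] %in% victims)
    out <- suppressMessages(remove_network_nodes(net, victims))
    expect_equal(network_edges(net) - network_edges(out), incident)
    expect_equal(network_size(out), network_size(net) - length(victims))
  }
})
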