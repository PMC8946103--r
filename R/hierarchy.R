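#' Seeded Louvain partition
#'
#' Two-phase Louvain modularity maximization on the unweighted graph.
#' Louvain's result depends on the vertex sweep order; to make runs
#' reproducible the vertices are put in sorted-id order and then shuffled
#' by the seeded RNG before the optimization, so a given
#' `(network, rng_seed)` pair always yields the same partition.
#'
#' @param net A network with at least one edge.
#' @param rng_seed Integer seed controlling the sweep order.
#' @return List with `communities` (list of member-id character vectors,
#'   ordered by smallest member) and `q`, the Newman-Girvan modularity
#'   `sum_c (e_c/m - (d_c/2m)^2)` of the partition.
#' @export
louvain_partition <- function(net, rng_seed = 42L) {
  if (igraph::ecount(net) == 0L) stop("cannot partition an edgeless network")
  membership <- with_seed(rng_seed, {
    ids <- sort(igraph::V(net)$name)
    perm <- sample(length(ids))
    # permute() wants, for each vertex, its new index; cluster_louvain
    # also draws from R's RNG, so it runs under the same seed
    shuffled <- igraph::permute(net, match(igraph::V(net)$name, ids[perm]))
    cl <- igraph::cluster_louvain(shuffled, resolution = 1)
    igraph::membership(cl)[igraph::V(net)$name]
  })
  q <- igraph::modularity(net, membership)
  comms <- split(names(membership), membership)
  comms <- unname(comms[order(vapply(comms, min, ""))])
  list(communities = comms, q = q)
}

new_community_node <- function(id, level, members, n_edges, q_of_split = NA_real_,
                               children = list(), is_motif = FALSE) {
  structure(list(id = id, level = level, members = members,
                 n_edges = n_edges, q_of_split = q_of_split,
                 children = children, is_motif = is_motif),
            class = "community_node")
}

#' Hierarchical Louvain decomposition with hub tracing
#'
#' Recursively partitions the network into nested communities, following
#' the network's high-degree hubs down to triangle motifs G(3,3). The root
#' community is level 0 (the whole network). A community is split by
#' seeded Louvain if it contains at least one hub (communities without
#' hubs are kept as undecomposed leaves unless `decompose_all = TRUE`);
#' recursion stops at triangle motifs, at communities with fewer than 3
#' nodes or 3 edges, when Louvain finds no improving split, or at
#' `max_levels`. A community of exactly 3 nodes and 2 edges (a path) is a
#' terminal leaf but not a motif: G(3,3) is read strictly as the triangle.
#'
#' Every hub's descent is recorded as a trace: the community path from the
#' root, the hub's degree `x[s]` inside each community's induced subgraph
#' (non-increasing with depth), and the level of the motif it ends in, if
#' any.
#'
#' @param net A non-empty network.
#' @param hub_threshold Degree floor defining hubs (>= 1), or `NULL` to use
#'   `hub_quantile`.
#' @param hub_quantile When `hub_threshold` is `NULL`: hubs are the nodes
#'   in this top fraction of the degree distribution (default 0.1).
#' @param rng_seed Base seed; each community split draws a deterministic
#'   derived seed so whole-tree builds are reproducible.
#' @param max_levels Recursion cap.
#' @param decompose_all Also split hub-free communities (diagnostics).
#' @return A `hierarchy_tree`: `root` (nested `community_node`s), `hubs`,
#'   `hub_threshold`, `traces` (per-hub), `max_depth`, `motif_levels`.
#' @export
decompose_network <- function(net, hub_threshold = NULL, hub_quantile = 0.1,
                              rng_seed = 42L, max_levels = 20L,
                              decompose_all = FALSE) {
  if (igraph::vcount(net) == 0L) stop("empty network")
  deg <- igraph::degree(net)
  if (is.null(hub_threshold)) {
    hub_threshold <- as.integer(stats::quantile(deg, 1 - hub_quantile,
                                                type = 1L))
    hub_threshold <- max(hub_threshold, 1L)
  }
  if (hub_threshold < 1L) stop("hub_threshold must be >= 1")
  hubs <- names(deg)[deg >= hub_threshold]

  counter <- new.env(parent = emptyenv())
  counter$i <- 0L
  next_seed <- function() {
    counter$i <- counter$i + 1L
    (as.integer(rng_seed) + counter$i * 1009L) %% .Machine$integer.max
  }

  build <- function(members, level, id) {
    sub <- igraph::induced_subgraph(net, members)
    n_e <- igraph::ecount(sub)
    is_motif <- length(members) == 3L && n_e == 3L
    node <- new_community_node(id, level, sort(members), n_e,
                               is_motif = is_motif)
    if (is_motif || length(members) < 3L || n_e < 3L) return(node)
    if (!decompose_all && !any(members %in% hubs)) return(node)
    if (level >= max_levels) return(node)
    part <- louvain_partition(sub, rng_seed = next_seed())
    if (length(part$communities) < 2L) return(node)
    node$q_of_split <- part$q
    node$children <- lapply(seq_along(part$communities), function(i) {
      build(part$communities[[i]], level + 1L, paste0(id, ".", i - 1L))
    })
    node
  }

  root <- build(igraph::V(net)$name, 0L, "0")

  traces <- lapply(hubs, function(h) trace_gene(root, net, h))
  names(traces) <- hubs
  motif_levels <- collect_motif_levels(root)
  structure(list(root = root, hubs = sort(hubs),
                 hub_threshold = hub_threshold,
                 traces = traces,
                 max_depth = tree_depth(root),
                 motif_levels = motif_levels,
                 rng_seed = as.integer(rng_seed)),
            class = "hierarchy_tree")
}

trace_gene <- function(root, net, gene) {
  path <- character(0)
  levels <- integer(0)
  x <- integer(0)
  n_edges <- integer(0)
  node <- root
  repeat {
    sub <- igraph::induced_subgraph(net, node$members)
    path <- c(path, node$id)
    levels <- c(levels, node$level)
    x <- c(x, unname(igraph::degree(sub)[gene]))
    n_edges <- c(n_edges, node$n_edges)
    if (length(node$children) == 0L) break
    hit <- NULL
    for (ch in node$children) {
      if (gene %in% ch$members) {
        hit <- ch
        break
      }
    }
    if (is.null(hit)) break
    node <- hit
  }
  structure(list(gene = gene,
                 degree_in_root = x[1L],
                 path = path, levels = levels,
                 x_by_level = x, n_edges_by_level = n_edges,
                 deepest_motif_level =
                   if (node$is_motif) node$level else NA_integer_),
            class = "hub_trace")
}

tree_depth <- function(node) {
  if (length(node$children) == 0L) return(node$level)
  max(vapply(node$children, tree_depth, 0L))
}

collect_motif_levels <- function(node) {
  own <- if (node$is_motif) node$level else integer(0)
  c(own, unlist(lapply(node$children, collect_motif_levels)))
}

#' @export
print.hierarchy_tree <- function(x, ...) {
  cat("hierarchy tree:", length(x$root$members), "nodes,",
      x$root$n_edges, "edges; depth", x$max_depth, "\n")
  cat(length(x$hubs), "hub(s) at degree >=", x$hub_threshold, ";",
      length(x$motif_levels), "motif leaf(s)\n")
  invisible(x)
}

#' Motif-localized hubs
#'
#' The hubs whose community trace terminates inside a triangle motif
#' G(3,3) at any hierarchy level.
#'
#' @param tree A `hierarchy_tree`.
#' @return Sorted character vector of gene ids (possibly empty).
#' @export
motif_localized_hubs <- function(tree) {
  hit <- vapply(tree$traces, function(t) !is.na(t$deepest_motif_level), TRUE)
  sort(names(tree$traces)[hit])
}

#' Key regulators
#'
#' Among the motif-localized hubs, those whose motif lies at the deepest
#' motif level reached by any hub — the deepest-rooted members of the
#' hierarchy.
#'
#' @param tree A `hierarchy_tree`.
#' @return Sorted character vector of gene ids.
#' @export
key_regulators <- function(tree) {
  mlh <- motif_localized_hubs(tree)
  if (length(mlh) == 0L) stop("no key regulators identifiable: no hub ends in a motif")
  lv <- vapply(tree$traces[mlh], function(t) t$deepest_motif_level, 0L)
  sort(mlh[lv == max(lv)])
}

#' Per-level edge-share profile P_KR of a gene
#'
#' For every level `s` on the gene's trace, `P_KR(x[s]) = x[s] / N[s]`:
#' the gene's degree inside the level-`s` community divided by that
#' community's edge count — the share of the community's links the gene
#' carries. For key regulators this share grows as the hierarchy deepens.
#'
#' @param tree A `hierarchy_tree` built by [decompose_network()].
#' @param net The network the tree was built from.
#' @param gene A node id present in the network.
#' @return Data frame with columns `level`, `x`, `n_edges`, `p_kr`.
#' @export
pkr_profile <- function(tree, net, gene) {
  if (!gene %in% igraph::V(net)$name) stop("gene not in network: ", gene)
  tr <- tree$traces[[gene]]
  if (is.null(tr)) tr <- trace_gene(tree$root, net, gene)
  data.frame(level = tr$levels, x = tr$x_by_level,
             n_edges = tr$n_edges_by_level,
             p_kr = tr$x_by_level / tr$n_edges_by_level)
}

#' Modularity by hierarchy level
#'
#' Mean Louvain modularity of the splits performed at each level of the
#' tree. Motif leaves are terminal and contribute no split; their count is
#' reported separately in the `n_motifs` attribute rather than averaged in
#' as zeros.
#'
#' @param tree A `hierarchy_tree`.
#' @return Data frame with columns `level`, `mean_q`, `n_communities`; the
#'   per-community values are attached as the `values` attribute.
#' @export
modularity_by_level <- function(tree) {
  acc <- new.env(parent = emptyenv())
  acc$rows <- list()
  walk <- function(node) {
    if (!is.na(node$q_of_split)) {
      acc$rows[[length(acc$rows) + 1L]] <-
        data.frame(level = node$level, q = node$q_of_split, id = node$id)
    }
    for (ch in node$children) walk(ch)
  }
  walk(tree$root)
  if (length(acc$rows) == 0L) {
    out <- data.frame(level = integer(0), mean_q = numeric(0),
                      n_communities = integer(0))
  } else {
    all_q <- do.call(rbind, acc$rows)
    lv <- sort(unique(all_q$level))
    out <- data.frame(
      level = lv,
      mean_q = vapply(lv, function(l) mean(all_q$q[all_q$level == l]), 0),
      n_communities = vapply(lv, function(l) sum(all_q$level == l), 0L))
    attr(out, "values") <- split(all_q$q, all_q$level)
  }
  attr(out, "n_motifs") <- length(tree$motif_levels)
  out
}

#' Export a hierarchy tree as JSON
#' @param tree A `hierarchy_tree`.
#' @param path Output path.
#' @param members Include full member lists (can be large).
#' @export
write_tree_json <- function(tree, path, members = FALSE) {
  strip <- function(node) {
    out <- list(id = node$id, level = node$level,
                size = length(node$members), n_edges = node$n_edges,
                q_of_split = if (is.na(node$q_of_split)) NULL
                             else node$q_of_split,
                is_motif = node$is_motif)
    if (members || node$is_motif) out$members <- node$members
    if (length(node$children) > 0L) out$children <- lapply(node$children, strip)
    out
  }
  jsonlite::write_json(list(hub_threshold = tree$hub_threshold,
                            hubs = tree$hubs, max_depth = tree$max_depth,
                            root = strip(tree$root)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
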