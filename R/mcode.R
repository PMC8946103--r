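#' MCODE parameters
#'
#' Parameter record for the molecular-complex-detection run, with the
#' stringent defaults used throughout this package: haircut on, fluff off,
#' degree cutoff 2, node score cutoff (vertex weight percentage) 0.2,
#' K-core 2, maximum BFS depth 100.
#'
#' @param degree_cutoff Minimum degree for a node to receive a non-zero
#'   weight (>= 1).
#' @param node_score_cutoff Vertex weight percentage in `[0, 1)`: a
#'   neighbor joins a growing complex if its weight is at least
#'   `(1 - node_score_cutoff)` times the seed's weight.
#' @param k_core Complexes must contain a k-core of this order (>= 2).
#' @param haircut Iteratively strip members with fewer than 2 connections
#'   inside the complex.
#' @param fluff Fluff post-processing (not used by the default pipeline).
#' @param max_depth BFS layer cap counted from the seed (>= 1).
#' @return A validated `mcode_params` list.
#' @export
mcode_params <- function(degree_cutoff = 2L, node_score_cutoff = 0.2,
                         k_core = 2L, haircut = TRUE, fluff = FALSE,
                         max_depth = 100L) {
  stopifnot(degree_cutoff >= 1L, node_score_cutoff >= 0,
            node_score_cutoff < 1, k_core >= 2L, max_depth >= 1L,
            is.logical(haircut), is.logical(fluff))
  structure(list(degree_cutoff = as.integer(degree_cutoff),
                 node_score_cutoff = node_score_cutoff,
                 k_core = as.integer(k_core), haircut = haircut,
                 fluff = fluff, max_depth = as.integer(max_depth)),
            class = "mcode_params")
}

graph_density_simple <- function(n, m) {
  if (n < 2L) return(0)
  2 * m / (n * (n - 1))
}

#' MCODE vertex weights
#'
#' Bader-Hogue local-density weighting: a node scoring below the degree
#' cutoff weighs 0; otherwise its weight is `k_max * density(H)` where
#' `H` is the highest k-core (core number `k_max`) of the subgraph induced
#' by the node's closed neighborhood (the node plus its neighbors).
#'
#' @param net A network.
#' @param params An `mcode_params` record.
#' @return A node measure `"mcode_weight"`.
#' @export
mcode_vertex_weights <- function(net, params = mcode_params()) {
  nodes <- igraph::V(net)$name
  deg <- igraph::degree(net)
  w <- numeric(length(nodes))
  names(w) <- nodes
  for (v in nodes[deg >= params$degree_cutoff]) {
    nb <- igraph::neighbors(net, v)$name
    gn <- igraph::induced_subgraph(net, c(v, nb))
    core <- igraph::coreness(gn)
    kmax <- max(core)
    hk <- names(core)[core == kmax]
    h <- igraph::induced_subgraph(gn, hk)
    w[v] <- kmax * graph_density_simple(igraph::vcount(h), igraph::ecount(h))
  }
  node_measure(w, "mcode_weight")
}

haircut_members <- function(net, members) {
  repeat {
    if (length(members) == 0L) return(members)
    sub <- igraph::induced_subgraph(net, members)
    d <- igraph::degree(sub)
    drop <- names(d)[d < 2L]
    if (length(drop) == 0L) return(members)
    members <- setdiff(members, drop)
  }
}

#' MCODE complex prediction
#'
#' Seeds are taken in order of decreasing vertex weight (ties broken by
#' lexicographic node id) over not-yet-assigned nodes. From each seed a
#' breadth-first traversal (at most `max_depth` layers) absorbs unassigned
#' neighbors whose weight is at least `(1 - node_score_cutoff)` times the
#' seed's weight; absorbed nodes are assigned to that complex, so
#' complexes are node-disjoint. Post-processing discards complexes lacking
#' a `k_core`-core and, when `haircut` is on, iteratively strips members
#' with fewer than 2 connections inside the complex. Density and score
#' (`density * size`) are computed on the final member set; complexes are
#' ranked by score descending (seed id ascending on ties).
#'
#' @param net A network.
#' @param params An `mcode_params` record.
#' @return List of `mcode_cluster` records (possibly empty), each with
#'   `members`, `seed`, `density`, `score`, `rank`.
#' @export
mcode_find_complexes <- function(net, params = mcode_params()) {
  w <- mcode_vertex_weights(net, params)
  nodes <- igraph::V(net)$name
  wv <- as.numeric(w[nodes])
  adj <- igraph::adjacent_vertices(net, nodes)
  adj <- lapply(adj, as.integer)
  order_idx <- order(-wv, nodes)
  assigned <- logical(length(nodes))
  raw <- list()
  for (si in order_idx) {
    if (assigned[si]) next
    thresh <- (1 - params$node_score_cutoff) * wv[si]
    members <- si
    frontier <- si
    checked <- logical(length(nodes))
    checked[si] <- TRUE
    depth <- 0L
    while (length(frontier) > 0L && depth < params$max_depth) {
      cand <- unique(unlist(adj[frontier], use.names = FALSE))
      cand <- cand[!checked[cand] & !assigned[cand]]
      checked[cand] <- TRUE
      nxt <- cand[wv[cand] >= thresh]
      members <- c(members, nxt)
      frontier <- nxt
      depth <- depth + 1L
    }
    assigned[members] <- TRUE
    raw[[length(raw) + 1L]] <- list(seed = nodes[si],
                                    members = nodes[members])
  }

  complexes <- list()
  for (cx in raw) {
    members <- cx$members
    if (length(members) < 2L) next
    sub <- igraph::induced_subgraph(net, members)
    if (max(igraph::coreness(sub)) < params$k_core) next
    if (params$haircut) {
      members <- haircut_members(net, members)
      if (length(members) < 2L) next
    }
    sub <- igraph::induced_subgraph(net, members)
    density <- graph_density_simple(igraph::vcount(sub), igraph::ecount(sub))
    complexes[[length(complexes) + 1L]] <-
      structure(list(members = sort(members), seed = cx$seed,
                     density = density,
                     score = density * length(members),
                     rank = NA_integer_),
                class = "mcode_cluster")
  }
  if (length(complexes) == 0L) return(complexes)
  o <- order(-vapply(complexes, function(x) x$score, 0),
             vapply(complexes, function(x) x$seed, ""))
  complexes <- complexes[o]
  for (i in seq_along(complexes)) complexes[[i]]$rank <- i
  complexes
}

#' @export
print.mcode_cluster <- function(x, ...) {
  cat(sprintf("MCODE cluster #%d: %d nodes, density %.3f, score %.3f (seed %s)\n",
              x$rank, length(x$members), x$density, x$score, x$seed))
  invisible(x)
}

#' Tabulate MCODE clusters
#' @param clusters List of `mcode_cluster` records.
#' @return Data frame with rank, score, density, size and members.
#' @export
mcode_cluster_table <- function(clusters) {
  if (length(clusters) == 0L) {
    return(data.frame(rank = integer(0), score = numeric(0),
                      density = numeric(0), size = integer(0),
                      seed = character(0), members = character(0)))
  }
  data.frame(
    rank = vapply(clusters, function(x) x$rank, 0L),
    score = vapply(clusters, function(x) x$score, 0),
    density = vapply(clusters, function(x) x$density, 0),
    size = vapply(clusters, function(x) length(x$members), 0L),
    seed = vapply(clusters, function(x) x$seed, ""),
    members = vapply(clusters, function(x) paste(x$members, collapse = ","),
                     ""))
}

#' Filter drug-associated genes through high-scoring complexes
#'
#' Returns the drug-associated genes that are members of any complex with
#' score at least `min_score` — the "filtered for noise" seed-gene set.
#' Raising `min_score` can only shrink the result.
#'
#' @param clusters List of `mcode_cluster` records.
#' @param ann A `node_annotations` table.
#' @param min_score Minimum complex score (default 10).
#' @return Sorted character vector of gene ids.
#' @export
filter_drug_genes <- function(clusters, ann, min_score = 10) {
  if (min_score < 0) stop("min_score must be >= 0")
  keep <- Filter(function(x) x$score >= min_score, clusters)
  members <- as.character(unique(unlist(lapply(keep, `[[`, "members"))))
  flagged <- ann$node[ann$drug_associated]
  sort(intersect(members, flagged))
}
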