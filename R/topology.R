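#' Degree profiles
#'
#' A degree profile aggregates a per-node quantity by exact degree class:
#' one row per observed degree `k`, holding the mean `value` over the
#' `count` contributing nodes. No logarithmic binning is applied; fitting
#' routines operate on these exact classes.
#'
#' @param k Integer degrees (strictly increasing, unique).
#' @param value Mean value at each degree.
#' @param count Number of contributing nodes per degree.
#' @param measure Name of the aggregated measure.
#' @return A `degree_profile` data frame.
#' @export
degree_profile <- function(k, value, count, measure) {
  stopifnot(length(k) == length(value), length(k) == length(count))
  o <- order(k)
  k <- as.integer(k[o])
  if (anyDuplicated(k)) stop("degree classes must be unique")
  out <- data.frame(k = k, value = as.numeric(value[o]),
                    count = as.integer(count[o]))
  attr(out, "measure") <- measure
  class(out) <- c("degree_profile", "data.frame")
  out
}

profile_from_nodes <- function(deg, values, measure) {
  ks <- sort(unique(deg))
  v <- vapply(ks, function(k) mean(values[deg == k]), 0)
  n <- vapply(ks, function(k) sum(deg == k), 0L)
  degree_profile(ks, v, n, measure)
}

#' Node-level measures
#'
#' A node measure is a named numeric vector (one finite value per node of
#' the source network) tagged with the measure's name.
#'
#' @param values Named numeric vector.
#' @param measure Measure name.
#' @export
node_measure <- function(values, measure) {
  if (is.null(names(values))) stop("node measure must be named")
  stopifnot(all(is.finite(values)))
  attr(values, "measure") <- measure
  values
}

#' Degree distribution p(k)
#'
#' Empirical probability `p(k) = n_k / N` where `n_k` is the number of nodes
#' of degree `k` and `N` the network size. Includes `k = 0` when isolated
#' nodes are present; the values sum to one.
#'
#' @param net A network.
#' @return A `degree_profile` for measure `"p"`.
#' @export
degree_distribution_profile <- function(net) {
  if (igraph::vcount(net) == 0L) stop("empty network")
  deg <- igraph::degree(net)
  tab <- table(deg)
  degree_profile(as.integer(names(tab)),
                 as.numeric(tab) / igraph::vcount(net),
                 as.integer(tab), "p")
}

#' Local clustering coefficient per node
#'
#' `c_i = 2 m_i / (k_i (k_i - 1))` with `m_i` the number of edges among
#' node `i`'s neighbors. Nodes of degree < 2 get `c_i = 0` by convention
#' (the ratio is undefined there).
#'
#' @param net A network.
#' @return A node measure `"c"`.
#' @export
local_clustering <- function(net) {
  vals <- igraph::transitivity(net, type = "local", isolates = "zero")
  names(vals) <- igraph::V(net)$name
  node_measure(vals, "c")
}

#' Clustering coefficient by degree c(k)
#'
#' Mean local clustering over nodes of each degree class. Nodes of degree
#' < 2 are excluded from the profile (their coefficient is undefined and
#' would otherwise drag log-scale fits); they still appear, as zeros, in
#' [local_clustering()].
#'
#' @param net A network.
#' @return A `degree_profile` for measure `"c"`.
#' @export
clustering_by_degree <- function(net) {
  if (igraph::vcount(net) == 0L) stop("empty network")
  cc <- local_clustering(net)
  deg <- igraph::degree(net)
  keep <- deg >= 2L
  if (!any(keep)) {
    return(degree_profile(integer(0), numeric(0), integer(0), "c"))
  }
  profile_from_nodes(deg[keep], as.numeric(cc)[keep], "c")
}

#' Neighborhood connectivity C_N(k)
#'
#' Per node, the mean degree of its neighbors; the profile reports the mean
#' of that quantity over nodes of each degree class. Isolated nodes have no
#' neighbors and are excluded.
#'
#' @param net A network.
#' @return A `degree_profile` for measure `"cn"`.
#' @export
neighborhood_connectivity <- function(net) {
  if (igraph::vcount(net) == 0L) stop("empty network")
  deg <- igraph::degree(net)
  keep <- deg >= 1L
  if (!any(keep)) {
    return(degree_profile(integer(0), numeric(0), integer(0), "cn"))
  }
  knn <- igraph::knn(net)$knn
  names(knn) <- igraph::V(net)$name
  profile_from_nodes(deg[keep], knn[keep], "cn")
}

#' Closeness centrality
#'
#' For node `m`, `C_C = n / sum_j d(m, j)` with the sum running over the
#' `n` other nodes of `m`'s connected component, i.e. the reciprocal mean
#' geodesic distance within the component. Computed component-wise so that
#' disconnected inputs carry no cross-component infinities; isolated nodes
#' score 0.
#'
#' @param net A network.
#' @return A node measure `"cc"`.
#' @export
closeness_centrality <- function(net) {
  if (igraph::vcount(net) == 0L) stop("empty network")
  comp <- igraph::components(net)
  vals <- numeric(igraph::vcount(net))
  names(vals) <- igraph::V(net)$name
  for (ci in seq_len(comp$no)) {
    members <- names(vals)[comp$membership == ci]
    if (length(members) < 2L) next
    sub <- igraph::induced_subgraph(net, members)
    cl <- igraph::closeness(sub, normalized = TRUE)
    vals[members] <- cl[members]
  }
  node_measure(vals, "cc")
}

#' Eigenvector centrality
#'
#' The non-negative principal eigenvector of the adjacency matrix of the
#' network's largest connected component, scaled to unit Euclidean norm;
#' nodes outside that component score 0. Computed by ARPACK iteration.
#'
#' @param net A network with at least one edge.
#' @param tol Convergence tolerance of the eigen iteration.
#' @param max_iter Iteration cap; non-convergence raises an error that
#'   reports the cap.
#' @return A node measure `"ce"`.
#' @export
eigenvector_centrality <- function(net, tol = 1e-10, max_iter = 3000L) {
  if (igraph::ecount(net) == 0L) stop("eigenvector centrality needs >= 1 edge")
  comp <- igraph::components(net)
  big <- which.max(comp$csize)
  members <- igraph::V(net)$name[comp$membership == big]
  sub <- igraph::induced_subgraph(net, members)
  # ARPACK draws its starting vector from R's RNG; fix it so the measure
  # is a pure function of the graph
  res <- tryCatch(
    with_seed(1L, igraph::eigen_centrality(
      sub, options = list(maxiter = as.integer(max_iter), tol = tol))),
    error = function(e) {
      stop("eigenvector centrality did not converge within ", max_iter,
           " iterations: ", conditionMessage(e))
    }
  )
  v <- abs(res$vector)
  v <- v / sqrt(sum(v^2))
  vals <- numeric(igraph::vcount(net))
  names(vals) <- igraph::V(net)$name
  vals[members] <- v[members]
  node_measure(vals, "ce")
}

#' Betweenness centrality
#'
#' `C_B(i) = sum_{j<k, j != i != k} g_jk(i) / g_jk`, the endpoint-excluding
#' shortest-path load. With `normalized = TRUE` (the default) each node's
#' value is divided by `(n - 1)(n - 2) / 2`, `n` being its own component's
#' size, bounding the measure by 1.
#'
#' @param net A network.
#' @param normalized Divide by the per-component pair count.
#' @return A node measure `"cb"`.
#' @export
betweenness_centrality <- function(net, normalized = TRUE) {
  if (igraph::vcount(net) == 0L) stop("empty network")
  vals <- igraph::betweenness(net, directed = FALSE, normalized = FALSE)
  names(vals) <- igraph::V(net)$name
  if (normalized) {
    comp <- igraph::components(net)
    sz <- comp$csize[comp$membership]
    denom <- (sz - 1) * (sz - 2) / 2
    vals <- ifelse(denom > 0, vals / denom, 0)
    names(vals) <- igraph::V(net)$name
  }
  node_measure(vals, "cb")
}

#' Aggregate a node measure by degree
#'
#' Mean of the measure over nodes of each degree `k >= 1`; this is the
#' measure-as-a-function-of-degree view used for log-log scaling fits.
#'
#' @param net The network the measure was computed on.
#' @param m A node measure defined on `net`'s nodes.
#' @return A `degree_profile` carrying the measure's name.
#' @export
bin_measure_by_degree <- function(net, m) {
  nodes <- igraph::V(net)$name
  if (!all(nodes %in% names(m))) stop("measure not defined on all nodes")
  deg <- igraph::degree(net)
  keep <- deg >= 1L
  if (!any(keep)) {
    return(degree_profile(integer(0), numeric(0), integer(0),
                          attr(m, "measure")))
  }
  profile_from_nodes(deg[keep], as.numeric(m[nodes])[keep],
                     attr(m, "measure"))
}

#' Export a degree profile or node measure as TSV
#' @param x A `degree_profile` or node measure.
#' @param path Output path.
#' @export
write_measure_tsv <- function(x, path) {
  if (inherits(x, "degree_profile")) {
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    utils::write.table(data.frame(node = names(x), value = as.numeric(x)),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
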