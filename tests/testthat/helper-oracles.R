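# Independent brute-force oracles, implemented on plain adjacency
# matrices so they share no code path with the package's igraph-backed
# measures.

# seeded Erdos-Renyi test graph as a package network
random_net <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(ids, 2L))
  keep <- stats::runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample(nrow(pairs), 1L)] <- TRUE
  as_network(pairs[keep, , drop = FALSE], isolates = ids)
}

adj_of <- function(net) {
  ids <- sort(igraph::V(net)$name)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  el <- igraph::as_edgelist(net)
  for (i in seq_len(nrow(el))) {
    A[el[i, 1L], el[i, 2L]] <- 1
    A[el[i, 2L], el[i, 1L]] <- 1
  }
  A
}

# all-pairs shortest-path lengths by Floyd-Warshall
bf_distances <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    Dk <- outer(D[, k], D[k, ], `+`)
    D <- pmin(D, Dk)
  }
  D
}

# number of shortest paths between every pair, by DP over distance
bf_path_counts <- function(A, D) {
  n <- nrow(A)
  S <- matrix(0, n, n, dimnames = dimnames(A))
  for (s in seq_len(n)) {
    S[s, s] <- 1
    reach <- which(is.finite(D[s, ]))
    for (v in reach[order(D[s, reach])]) {
      if (v == s) next
      preds <- which(A[, v] > 0 & D[s, ] == D[s, v] - 1)
      S[s, v] <- sum(S[s, preds])
    }
  }
  S
}

# endpoint-excluding betweenness, raw counts
bf_betweenness <- function(net) {
  A <- adj_of(net)
  D <- bf_distances(A)
  S <- bf_path_counts(A, D)
  ids <- rownames(A)
  n <- length(ids)
  out <- stats::setNames(numeric(n), ids)
  for (si in seq_len(n - 1L)) {
    for (ti in (si + 1L):n) {
      if (!is.finite(D[si, ti]) || S[si, ti] == 0) next
      for (vi in seq_len(n)) {
        if (vi == si || vi == ti) next
        if (is.finite(D[si, vi]) && is.finite(D[vi, ti]) &&
            D[si, vi] + D[vi, ti] == D[si, ti]) {
          out[vi] <- out[vi] + S[si, vi] * S[vi, ti] / S[si, ti]
        }
      }
    }
  }
  out
}

bf_closeness <- function(net) {
  A <- adj_of(net)
  D <- bf_distances(A)
  ids <- rownames(A)
  out <- stats::setNames(numeric(length(ids)), ids)
  for (i in seq_along(ids)) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    out[i] <- if (length(d) == 0L) 0 else length(d) / sum(d)
  }
  out
}

# local clustering via triangle counts from A^3
bf_clustering <- function(net) {
  A <- adj_of(net)
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  out <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
  stats::setNames(out, rownames(A))
}

# principal eigenvector of the largest component, unit L2 norm, by dense
# eigendecomposition
bf_eigen <- function(net) {
  comp <- igraph::components(net)
  big <- which.max(comp$csize)
  members <- igraph::V(net)$name[comp$membership == big]
  A <- adj_of(igraph::induced_subgraph(net, members))
  ev <- eigen(A, symmetric = TRUE)
  v <- abs(ev$vectors[, which.max(ev$values)])
  v <- v / sqrt(sum(v^2))
  out <- stats::setNames(numeric(igraph::vcount(net)), igraph::V(net)$name)
  out[rownames(A)] <- v
  out
}

# Newman-Girvan modularity of a membership vector
bf_modularity <- function(net, membership) {
  m <- igraph::ecount(net)
  el <- igraph::as_edgelist(net)
  deg <- igraph::degree(net)
  q <- 0
  for (c in unique(membership)) {
    inside <- names(membership)[membership == c]
    e_c <- sum(el[, 1L] %in% inside & el[, 2L] %in% inside)
    d_c <- sum(deg[inside])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# exact maximum modularity by exhaustive set-partition enumeration
# (feasible to ~8 nodes)
bf_max_modularity <- function(net) {
  ids <- igraph::V(net)$name
  n <- length(ids)
  stopifnot(n <= 9L)
  best <- -Inf
  # enumerate set partitions via restricted growth strings
  rgs <- integer(n)
  recurse <- function(i, maxv) {
    if (i > n) {
      memb <- stats::setNames(rgs, ids)
      q <- bf_modularity(net, memb)
      if (q > best) best <<- q
      return(invisible())
    }
    for (v in 0:(maxv + 1L)) {
      rgs[i] <<- v
      recurse(i + 1L, max(maxv, v))
    }
  }
  recurse(1L, -1L)
  best
}

# independent k-core check: repeatedly strip nodes of degree < k
bf_has_kcore <- function(net, members, k) {
  sub <- igraph::induced_subgraph(net, members)
  repeat {
    d <- igraph::degree(sub)
    drop <- names(d)[d < k]
    if (length(drop) == 0L) return(igraph::vcount(sub) > 0L)
    if (length(drop) == igraph::vcount(sub)) return(FALSE)
    sub <- igraph::delete_vertices(sub, drop)
  }
}
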