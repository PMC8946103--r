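#' Deterministic hierarchical (Ravasz) module network
#'
#' The iterated module construction that produces hierarchical scale-free
#' topology: level 1 is a `base`-clique; each further level creates
#' `base - 1` replicas of the current module and wires every replica's
#' peripheral nodes to the original central hub. The resulting network has
#' exactly `base^levels` nodes and exhibits the `c(k) ~ k^-1` clustering
#' signature diagnostic of hierarchical organization.
#'
#' @param levels Number of construction levels (1..5).
#' @param base Module size (>= 3; default 5).
#' @return A network with nodes `r1..rN`.
#' @export
ravasz_network <- function(levels = 3L, base = 5L) {
  stopifnot(levels >= 1L, base >= 3L)
  if (base^levels > 4000) stop("size guard: base^levels must be <= 4000")
  center <- 1L
  peripheral <- 2:base
  edges <- t(utils::combn(seq_len(base), 2L))
  n_mod <- base
  for (lv in seq_len(levels - 1L)) {
    new_edges <- list(edges)
    new_peripheral <- integer(0)
    for (r in seq_len(base - 1L)) {
      offset <- r * n_mod
      new_edges[[r + 1L]] <- edges + offset
      new_peripheral <- c(new_peripheral, peripheral + offset)
    }
    hub_links <- cbind(center, new_peripheral)
    edges <- rbind(do.call(rbind, new_edges), hub_links)
    peripheral <- new_peripheral
    n_mod <- n_mod * base
  }
  as_network(cbind(paste0("r", edges[, 1L]), paste0("r", edges[, 2L])),
             name = sprintf("ravasz_%d_%d", levels, base))
}

#' Preferential-attachment (Barabasi-Albert) network
#'
#' Growth from an `m`-clique seed: each new node attaches to `m` distinct
#' existing nodes chosen with probability proportional to their current
#' degree (uniformly while all degrees are zero). The result has exactly
#' `(n - m) m + choose(m, 2)` edges and a degree distribution with
#' power-law tail of exponent ~3.
#'
#' @param n Number of nodes.
#' @param m Edges per new node (`1 <= m < n`).
#' @param rng_seed Integer seed.
#' @return A network with nodes `v1..vn`.
#' @export
ba_network <- function(n, m, rng_seed = 42L) {
  if (m < 1L || m >= n) stop("need 1 <= m < n")
  with_seed(rng_seed, {
    deg <- integer(n)
    if (m >= 2L) {
      seed_edges <- t(utils::combn(seq_len(m), 2L))
      deg[seq_len(m)] <- m - 1L
    } else {
      seed_edges <- matrix(integer(0), ncol = 2L)
    }
    edges <- matrix(0L, nrow = (n - m) * m + nrow(seed_edges), ncol = 2L)
    if (nrow(seed_edges) > 0L) edges[seq_len(nrow(seed_edges)), ] <- seed_edges
    at <- nrow(seed_edges)
    for (t in (m + 1L):n) {
      existing <- seq_len(t - 1L)
      prob <- deg[existing]
      targets <- if (sum(prob) == 0)
        sample(existing, m)
      else
        sample(existing, m, prob = prob)
      edges[at + seq_len(m), ] <- cbind(t, targets)
      at <- at + m
      deg[targets] <- deg[targets] + 1L
      deg[t] <- deg[t] + m
    }
    as_network(cbind(paste0("v", edges[, 1L]), paste0("v", edges[, 2L])),
               name = sprintf("ba_%d_%d", n, m))
  })
}

#' Seeded draws from the discrete power-law distribution
#'
#' i.i.d. samples from `P(X = x) = x^(-alpha) / zeta(alpha, xmin)` for
#' integer `x >= xmin`, by inverse transform on the Hurwitz-zeta
#' normalized pmf (exact over the tabulated support up to 1e6; the
#' residual tail mass, below ~1e-7 for the exponents of interest, falls
#' back to the continuous approximation).
#'
#' @param alpha Exponent (> 1).
#' @param xmin Lower cutoff (integer >= 1).
#' @param n Number of draws (>= 1).
#' @param rng_seed Integer seed.
#' @return Integer vector of length `n`, all values >= `xmin`.
#' @export
powerlaw_samples <- function(alpha, xmin = 1L, n, rng_seed = 42L) {
  stopifnot(alpha > 1, xmin >= 1L, n >= 1L)
  with_seed(rng_seed, sample_discrete_powerlaw(alpha, as.integer(xmin), n))
}

# Bernoulli edge sampling between (or within) node sets, by drawing the
# binomial edge count and sampling index pairs (collisions removed, so
# realized counts can fall a hair below p * npairs at these densities).
sample_block_edges <- function(a, b = NULL, p) {
  if (p <= 0) return(NULL)
  if (is.null(b)) {
    npairs <- length(a) * (length(a) - 1L) / 2
    if (npairs < 1) return(NULL)
    if (length(a) <= 80L) {
      pr <- t(utils::combn(a, 2L))
      keep <- stats::runif(nrow(pr)) < p
      return(if (any(keep)) pr[keep, , drop = FALSE] else NULL)
    }
    m <- stats::rbinom(1L, npairs, p)
    if (m == 0L) return(NULL)
    i <- sample(a, m, replace = TRUE)
    j <- sample(a, m, replace = TRUE)
    keep <- i != j
    pr <- unique(cbind(pmin(i[keep], j[keep]), pmax(i[keep], j[keep])))
    return(pr)
  }
  npairs <- length(a) * length(b)
  m <- stats::rbinom(1L, npairs, p)
  if (m == 0L) return(NULL)
  pr <- unique(cbind(sample(a, m, replace = TRUE),
                     sample(b, m, replace = TRUE)))
  pr
}

default_chain_spec <- function(depth) {
  # Sibling shells get denser (and smaller) with depth: the
  # community-forming, assortative regime. The hub triangle rides the
  # chain of shells downward — at every split its pull into the
  # continuing shell exceeds any single sibling block's pull, while each
  # block's modularity mass penalty keeps the hubs out of the blocks —
  # and separates as the terminal motif leaf when the innermost shell
  # splits. Blocks are kept sparse enough that a block node dragged along
  # by its hub edge always profits from returning home, so no straggler
  # corrupts the motif.
  if (depth < 2L) stop("motif depth must be >= 2")
  n_lev <- depth - 1L # sibling levels; chain communities are C_1..C_{depth-1}
  lv <- seq_len(n_lev)
  list(
    n_sib = c(8L, rep(4L, max(0L, n_lev - 1L)))[lv],
    sib_size = c(60L, 35L, rep(30L, max(0L, n_lev - 2L)))[lv],
    p_sib = c(0.15, 0.22, rep(0.3, max(0L, n_lev - 2L)))[lv],
    p_glue = c(0.015, 0.04, rep(0.08, max(0L, n_lev - 2L)))[lv],
    a_sib = c(2L, rep(1L, max(0L, n_lev - 1L)))[lv] # hub edges per block
  )
}

#' Planted hub hierarchy with ground truth
#'
#' Seeded generator for the nested-community, hub-dominated networks this
#' pipeline is designed for. The graph is a union of (i) background
#' stochastic blocks whose internal densities follow a gradient (giving a
#' decaying degree distribution and assortative degree mixing), (ii) one
#' "chain" of nested shells per requested motif depth — sibling blocks
#' plus an increasingly dense continuation, terminating in a dense deep
#' block — and (iii) one planted hub triangle per chain, wired to a large
#' share of every shell so the hubs' degrees clear the declared hub floor
#' while their strongest per-community pull always points down the chain.
#' Iterative Louvain decomposition therefore traces the hubs into their
#' triangle, which surfaces as a motif leaf at the deepest level.
#'
#' Probabilities must be strictly ordered so deeper shells are denser;
#' degenerate orderings are rejected.
#'
#' @param motif_depths Integer vector (>= 2), one planted hub triangle per
#'   entry, at that intended hierarchy depth. Default 3.
#' @param n_background Number of background blocks (default 60).
#' @param background_size Nodes per background block (default 55).
#' @param p_background Length-2 density range for the background gradient.
#' @param p_sprinkle Global noise-edge probability across all node pairs.
#' @param n_dense,dense_size,p_dense Free-standing dense blocks (the
#'   drug-gene-rich protein-complex analogues the MCODE stage detects).
#' @param chain_specs Optional list (one element per chain) overriding
#'   the per-chain defaults; see `default_chain_spec`.
#' @param rng_seed Integer seed; the generator is a pure function of its
#'   parameters and this seed.
#' @return List with `network` and `truth` (a `planted_truth`: hub ids,
#'   motif triples by intended depth, declared `hub_floor`, dense-region
#'   node ids, generator parameters and seed).
#' @export
planted_hub_hierarchy <- function(motif_depths = 3L,
                                  n_background = 60L,
                                  background_size = 55L,
                                  p_background = c(0.04, 0.15),
                                  p_sprinkle = 5e-4,
                                  n_dense = 3L, dense_size = 14L,
                                  p_dense = 0.92,
                                  chain_specs = NULL,
                                  rng_seed = 42L) {
  stopifnot(all(motif_depths >= 2L), n_background >= 1L)
  if (diff(p_background) <= 0) {
    stop("degenerate probabilities: background gradient must increase")
  }
  specs <- lapply(seq_along(motif_depths), function(i) {
    sp <- default_chain_spec(motif_depths[i])
    if (!is.null(chain_specs) && length(chain_specs) >= i &&
        !is.null(chain_specs[[i]])) {
      sp <- utils::modifyList(sp, chain_specs[[i]])
    }
    if (any(diff(sp$p_sib) <= 0) && length(sp$p_sib) > 1L) {
      stop("degenerate probabilities: deeper shells must be denser")
    }
    stopifnot(all(sp$a_sib >= 1L), all(sp$n_sib >= 2L))
    sp
  })

  with_seed(rng_seed, {
    edges <- list()
    nodes <- character(0)
    add_edges <- function(e) {
      if (!is.null(e) && nrow(e) > 0) edges[[length(edges) + 1L]] <<- e
    }

    # Nodes a hub may wire to: well above-average internal degree in
    # their own block, so no wiring target ever profits from following
    # the hub out of its community (a dragged-along target would end as a
    # pendant on the hub triangle and corrupt the motif).
    solid_of <- function(blk, e, min_deg = 3L) {
      if (is.null(e)) return(blk)
      d <- table(factor(c(e[, 1L], e[, 2L]), levels = blk))
      ord <- names(sort(d, decreasing = TRUE)) # ties break by node id
      keep <- d[ord] >= min_deg
      if (sum(keep) >= 9L) ord[keep] else ord[seq_len(min(9L, length(ord)))]
    }

    # background blocks on a density gradient
    p_bg <- seq(p_background[1L], p_background[2L],
                length.out = n_background)
    bg_blocks <- list()
    bg_solid <- list()
    for (b in seq_len(n_background)) {
      ids <- sprintf("B%02d_n%02d", b, seq_len(background_size))
      bg_blocks[[b]] <- ids
      nodes <- c(nodes, ids)
      e <- sample_block_edges(ids, p = p_bg[b])
      add_edges(e)
      bg_solid[[b]] <- solid_of(ids, e, 5L)
    }

    hub_ids <- character(0)
    motif_members <- list()
    dense_nodes <- character(0)
    hub_degree_target <- integer(0)

    for (ci in seq_along(motif_depths)) {
      sp <- specs[[ci]]
      depth <- motif_depths[ci]
      n_lev <- depth - 1L
      pre <- sprintf("C%d", ci)

      # sibling shells: level l (1 = outermost) has n_sib[l] blocks
      sib_nodes <- if (n_lev > 0L) vector("list", n_lev) else list()
      sib_solid <- sib_nodes
      for (l in seq_len(n_lev)) {
        sib_nodes[[l]] <- lapply(seq_len(sp$n_sib[l]), function(s) {
          sprintf("%s_L%d_S%d_n%02d", pre, l, s, seq_len(sp$sib_size[l]))
        })
        sib_solid[[l]] <- vector("list", sp$n_sib[l])
        min_deg <- max(3L, ceiling(sp$p_sib[l] * (sp$sib_size[l] - 1L)) + 1L)
        for (s in seq_len(sp$n_sib[l])) {
          blk <- sib_nodes[[l]][[s]]
          nodes <- c(nodes, blk)
          e <- sample_block_edges(blk, p = sp$p_sib[l])
          add_edges(e)
          sib_solid[[l]][[s]] <- solid_of(blk, e, min_deg)
        }
      }

      hubs <- sprintf("%s_H%d", pre, 1:3)
      nodes <- c(nodes, hubs)
      hub_ids <- c(hub_ids, hubs)
      motif_members[[as.character(depth)]] <-
        c(motif_members[[as.character(depth)]], list(hubs))
      add_edges(cbind(hubs[c(1L, 1L, 2L)], hubs[c(2L, 3L, 3L)]))

      # Glue inside each chain community so shells merge at the parent's
      # scale but split at their own. Downward glue reaches only the next
      # level's shell: gluing all deeper shells would pile degree onto
      # the small innermost blocks and push them past the hub floor.
      for (l in seq_len(n_lev)) {
        if (sp$n_sib[l] > 1L) {
          for (s1 in seq_len(sp$n_sib[l] - 1L)) {
            for (s2 in (s1 + 1L):sp$n_sib[l]) {
              add_edges(sample_block_edges(sib_nodes[[l]][[s1]],
                                           sib_nodes[[l]][[s2]],
                                           sp$p_glue[l]))
            }
          }
        }
        if (l < n_lev) {
          add_edges(sample_block_edges(unlist(sib_nodes[[l]]),
                                       unlist(sib_nodes[[l + 1L]]),
                                       sp$p_glue[l]))
        }
      }

      # Hub wiring. Per community, a hub's edges into the continuing
      # chain exceed its edges into any sibling block, while each
      # sibling-block pull stays below that block's modularity mass
      # penalty. A thin spread over background blocks tops up the hub
      # degree without competing with the chain at the root split.
      # Wiring targets are disjoint across the three hubs: a node with
      # edges to two or more hubs would defect into the triangle
      # community and corrupt the motif.
      # `blk` arrives ordered by internal degree: the most firmly homed
      # nodes take the hub edges
      wire_disjoint <- function(blk, per_hub) {
        per_hub <- min(per_hub, floor(length(blk) / 3))
        if (per_hub < 1L) return(0L)
        slots <- blk[seq_len(3L * per_hub)]
        for (i in 1:3) {
          add_edges(cbind(hubs[i],
                          slots[((i - 1L) * per_hub + 1L):(i * per_hub)]))
        }
        per_hub
      }
      wired <- 0L
      for (l in seq_len(n_lev)) {
        for (blk in sib_solid[[l]]) {
          wired <- wired + wire_disjoint(blk, sp$a_sib[l])
        }
      }
      # only the denser background blocks: their nodes are firmly enough
      # homed that a single hub edge never pulls them out
      for (b in seq(n_background %/% 2 + 1L, n_background)) {
        wired <- wired + wire_disjoint(bg_solid[[b]], 1L)
      }
      hub_degree_target <- c(hub_degree_target, rep(wired + 2L, 3L))
    }

    # free-standing dense blocks: the drug-gene-rich complexes the MCODE
    # stage is meant to find
    dense_blocks <- lapply(seq_len(n_dense), function(d) {
      sprintf("D%d_n%02d", d, seq_len(dense_size))
    })
    for (blk in dense_blocks) {
      nodes <- c(nodes, blk)
      dense_nodes <- c(dense_nodes, blk)
      add_edges(sample_block_edges(blk, p = p_dense))
    }

    # global sprinkle over non-hub nodes (a sprinkle edge onto a hub
    # would drag its low-degree partner down the hub's trace)
    idx <- which(!nodes %in% hub_ids)
    spr <- sample_block_edges(idx, p = p_sprinkle)
    if (!is.null(spr)) add_edges(cbind(nodes[spr[, 1L]], nodes[spr[, 2L]]))

    net <- suppressMessages(
      as_network(do.call(rbind, edges), name = "planted_hub_hierarchy",
                 isolates = nodes))
    deg <- igraph::degree(net)
    max_other <- max(deg[setdiff(names(deg), hub_ids)])
    min_hub <- min(deg[hub_ids])
    if (max_other >= min_hub) {
      stop("degree separation failed: a non-hub node reaches degree ",
           max_other, " but the weakest hub only ", min_hub)
    }
    hub_floor <- as.integer((max_other + min_hub) %/% 2L)
    truth <- structure(list(
      planted_hub_ids = sort(hub_ids),
      planted_motif_members = motif_members,
      drug_gene_ids = character(0),
      dense_nodes = sort(dense_nodes),
      hub_floor = hub_floor,
      generator = "planted_hub_hierarchy",
      params = list(motif_depths = motif_depths,
                    n_background = n_background,
                    background_size = background_size,
                    p_background = p_background,
                    p_sprinkle = p_sprinkle,
                    n_dense = n_dense, dense_size = dense_size,
                    p_dense = p_dense),
      rng_seed = as.integer(rng_seed)), class = "planted_truth")
    # emission-time consistency checks
    stopifnot(all(deg[hub_ids] > hub_floor))
    for (tri in unlist(truth$planted_motif_members, recursive = FALSE)) {
      sub <- igraph::induced_subgraph(net, tri)
      stopifnot(igraph::vcount(sub) == 3L, igraph::ecount(sub) == 3L)
    }
    list(network = net, truth = truth)
  })
}

#' Annotate drug-associated genes on a planted network
#'
#' Flags a fraction of the planted dense-region nodes and a (small)
#' background fraction of all remaining nodes as drug-associated —
#' emulating a noisy drug-target list concentrated in dense complexes.
#'
#' @param net The network.
#' @param truth The `planted_truth` emitted with it.
#' @param frac_in_dense Fraction of dense-region nodes to flag.
#' @param frac_background Fraction of all other nodes to flag.
#' @param rng_seed Integer seed.
#' @return A `node_annotations` table covering every node of `net`.
#' @export
annotate_drug_genes <- function(net, truth, frac_in_dense = 0.8,
                                frac_background = 0.05, rng_seed = 42L) {
  stopifnot(frac_in_dense >= 0, frac_in_dense <= 1,
            frac_background >= 0, frac_background <= 1)
  all_nodes <- igraph::V(net)$name
  dense <- intersect(truth$dense_nodes, all_nodes)
  rest <- setdiff(all_nodes, dense)
  with_seed(rng_seed, {
    flagged <- c(sample(dense, round(frac_in_dense * length(dense))),
                 sample(rest, round(frac_background * length(rest))))
    node_annotations(all_nodes, all_nodes %in% flagged)
  })
}
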