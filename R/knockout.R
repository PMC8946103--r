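#' Cumulative level-wise hub knockout experiment
#'
#' Groups the network's motif-localized hubs by the hierarchy level of
#' their deepest motif, then removes one group per step — cumulatively, in
#' the configured level order — and re-characterizes the surviving
#' network's topology after every step. Step 0 records the intact network.
#' Nodes isolated by a removal are kept in the graph but excluded from the
#' scaling fits; a fit that loses statistical support after removals is
#' recorded as absent rather than extrapolated.
#'
#' @param net The network the tree was built from.
#' @param tree A `hierarchy_tree` with at least one motif-localized hub.
#' @param order `"shallow_to_deep"` (default), `"deep_to_shallow"`, or
#'   `"paper_3_to_6"` which restricts the eliminations to motif levels
#'   3..6 counted from the whole network at level 0.
#' @param rng_seed Seed passed to each step's topology summary.
#' @param n_boot Bootstrap replicates per step (0 = skip p-values; the
#'   fast default for trajectories).
#' @param thresholds Classification thresholds, see [classify_topology()].
#' @return A `knockout_trajectory`: list of steps, each with `step`,
#'   `level_eliminated`, `removed`, `cumulative_removed`, `node_count`,
#'   `edge_count`, `newly_isolated` and a `topology_summary`.
#' @export
run_knockout <- function(net, tree,
                         order = c("shallow_to_deep", "deep_to_shallow",
                                   "paper_3_to_6"),
                         rng_seed = 42L, n_boot = 0L,
                         thresholds = list(gof_max = 0.33, p_min = 0.1,
                                           flat_band = 0.25)) {
  order <- match.arg(order)
  mlh <- motif_localized_hubs(tree)
  if (length(mlh) == 0L) stop("no motif-localized hubs to knock out")
  lv <- vapply(tree$traces[mlh], function(t) t$deepest_motif_level, 0L)
  levels_present <- sort(unique(lv))
  if (order == "deep_to_shallow") levels_present <- rev(levels_present)
  if (order == "paper_3_to_6") {
    levels_present <- levels_present[levels_present >= 3L &
                                       levels_present <= 6L]
    if (length(levels_present) == 0L) {
      stop("no motif-localized hubs in levels 3..6")
    }
  }

  summarize_step <- function(g) {
    summarize_topology(g, n_boot = n_boot, rng_seed = rng_seed,
                       thresholds = thresholds)
  }
  steps <- list(list(step = 0L, level_eliminated = NA_integer_,
                     removed = character(0), cumulative_removed = 0L,
                     node_count = igraph::vcount(net),
                     edge_count = igraph::ecount(net),
                     newly_isolated = 0L,
                     summary = summarize_step(net)))
  current <- net
  cum <- 0L
  for (i in seq_along(levels_present)) {
    l <- levels_present[i]
    victims <- sort(mlh[lv == l])
    if (length(victims) == igraph::vcount(current)) {
      stop("elimination at level ", l, " would empty the network")
    }
    current <- remove_network_nodes(current, victims, quiet = TRUE)
    cum <- cum + length(victims)
    steps[[i + 1L]] <- list(step = i, level_eliminated = l,
                            removed = victims, cumulative_removed = cum,
                            node_count = igraph::vcount(current),
                            edge_count = igraph::ecount(current),
                            newly_isolated =
                              attr(current, "newly_isolated") %||% 0L,
                            summary = summarize_step(current))
  }
  structure(list(steps = steps, order = order,
                 rng_seed = as.integer(rng_seed)),
            class = "knockout_trajectory")
}

#' Tabulate a knockout trajectory
#'
#' One row per step: the elimination bookkeeping, the six fitted scaling
#' exponents (NA where a fit lost support) and the topology class.
#'
#' @param traj A `knockout_trajectory`.
#' @return A data frame suitable for TSV export / re-plotting.
#' @export
knockout_table <- function(traj) {
  exp_of <- function(s, key) {
    f <- s$summary$fits[[key]]
    if (is.null(f)) NA_real_ else f$exponent
  }
  do.call(rbind, lapply(traj$steps, function(s) {
    data.frame(step = s$step,
               level = if (is.na(s$level_eliminated)) NA_integer_
                       else s$level_eliminated,
               n_removed = length(s$removed),
               cumulative_removed = s$cumulative_removed,
               nodes = s$node_count, edges = s$edge_count,
               newly_isolated = s$newly_isolated,
               exp_p = exp_of(s, "p"), exp_c = exp_of(s, "c"),
               exp_cn = exp_of(s, "cn"), exp_cb = exp_of(s, "cb"),
               exp_cc = exp_of(s, "cc"), exp_ce = exp_of(s, "ce"),
               topology_class = s$summary$topology_class)
  }))
}

#' @export
print.knockout_trajectory <- function(x, ...) {
  cat("knockout trajectory (", x$order, "): ",
      length(x$steps) - 1L, " elimination step(s)\n", sep = "")
  print(knockout_table(x)[, c("step", "level", "n_removed", "nodes",
                              "edges", "exp_p", "exp_c",
                              "topology_class")])
  invisible(x)
}
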