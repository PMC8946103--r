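#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis with the defaults
#' used throughout: fit quality thresholds (goodness-of-fit <= 0.33,
#' bootstrap p >= 0.1), MCODE complex score floor 10 for drug-gene
#' filtering, betweenness cutoff 0.010 for resultant-network hub ranking,
#' and the bootstrap size 2500. The resolved configuration is serialized
#' next to every run's outputs so no threshold is hidden.
#'
#' @param edge_list,annotations Input file paths, or `NULL` to use the
#'   synthetic preset generator.
#' @param hub_threshold Degree floor for hubs; `NULL` means the top
#'   `hub_quantile` of degrees.
#' @param hub_quantile Hub fraction when `hub_threshold` is `NULL`.
#' @param rng_seed Seed for every stochastic stage.
#' @param max_levels Hierarchy recursion cap.
#' @param mcode An `mcode_params` record.
#' @param min_cluster_score Complex score floor for the drug-gene filter.
#' @param knockout_order See [run_knockout()].
#' @param n_boot Bootstrap replicates for the intact-network degree fit.
#' @param gof_max,p_min,flat_band Classification thresholds.
#' @param cb_cutoff Rounded betweenness floor for resultant-network hubs.
#' @param out_dir Output directory (created if needed), or `NULL` for no
#'   file output.
#' @return A validated `run_config` list.
#' @export
run_config <- function(edge_list = NULL, annotations = NULL,
                       hub_threshold = NULL, hub_quantile = 0.1,
                       rng_seed = 42L, max_levels = 20L,
                       mcode = mcode_params(), min_cluster_score = 10,
                       knockout_order = "shallow_to_deep",
                       n_boot = 2500L, gof_max = 0.33, p_min = 0.1,
                       flat_band = 0.25, cb_cutoff = 0.010,
                       out_dir = NULL) {
  if (!is.null(edge_list) && !file.exists(edge_list)) {
    config_error("edge_list file not found: ", edge_list)
  }
  if (!is.null(annotations) && !file.exists(annotations)) {
    config_error("annotations file not found: ", annotations)
  }
  if (!inherits(mcode, "mcode_params")) {
    config_error("mcode must be an mcode_params record")
  }
  if (!knockout_order %in% c("shallow_to_deep", "deep_to_shallow",
                             "paper_3_to_6")) {
    config_error("unknown knockout_order: ", knockout_order)
  }
  if (min_cluster_score < 0 || n_boot < 0 || gof_max <= 0 ||
      p_min < 0 || p_min > 1 || flat_band < 0) {
    config_error("threshold out of range")
  }
  structure(list(edge_list = edge_list, annotations = annotations,
                 hub_threshold = hub_threshold,
                 hub_quantile = hub_quantile,
                 rng_seed = as.integer(rng_seed),
                 max_levels = as.integer(max_levels), mcode = mcode,
                 min_cluster_score = min_cluster_score,
                 knockout_order = knockout_order,
                 n_boot = as.integer(n_boot), gof_max = gof_max,
                 p_min = p_min, flat_band = flat_band,
                 cb_cutoff = cb_cutoff, out_dir = out_dir),
            class = "run_config")
}

#' End-to-end network analysis
#'
#' Runs the whole pipeline on an input edge list (plus drug-gene
#' annotations) or, by default, on the synthetic planted-hierarchy preset:
#' topology characterization and scaling fits, hierarchical hub tracing
#' with the key-regulator report, MCODE complex detection and drug-gene
#' filtering, the cumulative knockout experiment, and the resultant
#' network of motif-localized hubs plus filtered drug genes. Stage
#' artifacts (TSV/JSON) and a single summary JSON are written to
#' `cfg$out_dir` when set; a failing stage aborts with a
#' `hubtrace_stage_error` naming the stage, leaving earlier artifacts in
#' place. Runs are deterministic given the configuration seed.
#'
#' @param cfg A `run_config`.
#' @return Invisibly, a list with every stage result and the summary.
#' @export
run_pdn_analysis <- function(cfg = run_config()) {
  if (!inherits(cfg, "run_config")) config_error("cfg must be a run_config")
  out <- cfg$out_dir
  if (!is.null(out) && !dir.exists(out)) {
    dir.create(out, recursive = TRUE)
  }
  emit <- function(writer, x, file) {
    if (!is.null(out)) writer(x, file.path(out, file))
  }
  in_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, c("hubtrace_stage_error", "hubtrace_data_error",
                        "hubtrace_config_error"))) {
        stop(e)
      }
      stage_error(stage, e)
    })
  }

  # --- input stage -----------------------------------------------------
  truth <- NULL
  input <- in_stage("input", {
    if (is.null(cfg$edge_list)) {
      gen <- planted_hub_hierarchy(rng_seed = cfg$rng_seed)
      truth <- gen$truth
      ann <- annotate_drug_genes(gen$network, gen$truth,
                                 rng_seed = cfg$rng_seed)
      # the preset declares its own hub floor; only an explicit
      # hub_threshold overrides it
      if (is.null(cfg$hub_threshold)) {
        cfg$hub_threshold <- gen$truth$hub_floor
      }
      list(net = gen$network, ann = ann)
    } else {
      net <- tryCatch(read_edge_list(cfg$edge_list),
                      error = function(e) data_error(conditionMessage(e)))
      ann <- if (is.null(cfg$annotations)) {
        node_annotations(character(0))
      } else {
        tryCatch(read_annotations(cfg$annotations),
                 error = function(e) data_error(conditionMessage(e)))
      }
      list(net = net, ann = ann)
    }
  })
  net <- input$net
  if (!is.null(out)) {
    jsonlite::write_json(config_as_list(cfg), file.path(out, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  thresholds <- list(gof_max = cfg$gof_max, p_min = cfg$p_min,
                     flat_band = cfg$flat_band)

  # --- topology + scaling ---------------------------------------------
  topo <- in_stage("topology", {
    summarize_topology(net, n_boot = cfg$n_boot, rng_seed = cfg$rng_seed,
                       thresholds = thresholds)
  })
  emit(write_topology_json, topo, "topology.json")

  # --- hierarchy / key regulators -------------------------------------
  tree <- in_stage("hierarchy", {
    decompose_network(net, hub_threshold = cfg$hub_threshold,
                      hub_quantile = cfg$hub_quantile,
                      rng_seed = cfg$rng_seed,
                      max_levels = cfg$max_levels)
  })
  kr_report <- in_stage("hierarchy", {
    mlh <- motif_localized_hubs(tree)
    krs <- if (length(mlh) > 0L) key_regulators(tree) else character(0)
    list(hub_threshold = tree$hub_threshold,
         n_hubs = length(tree$hubs),
         motif_localized_hubs = mlh, key_regulators = krs,
         max_depth = tree$max_depth,
         modularity_by_level = modularity_by_level(tree),
         pkr = lapply(stats::setNames(krs, krs), function(g) {
           pkr_profile(tree, net, g)
         }))
  })
  if (!is.null(out)) {
    write_tree_json(tree, file.path(out, "hierarchy.json"))
    jsonlite::write_json(
      list(hub_threshold = kr_report$hub_threshold,
           n_hubs = kr_report$n_hubs,
           motif_localized_hubs = kr_report$motif_localized_hubs,
           key_regulators = kr_report$key_regulators,
           max_depth = kr_report$max_depth,
           modularity_by_level = kr_report$modularity_by_level,
           pkr = kr_report$pkr),
      file.path(out, "key_regulators.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "columns")
  }

  # --- MCODE + drug-gene filter ---------------------------------------
  mcode_res <- in_stage("mcode", {
    clusters <- mcode_find_complexes(net, cfg$mcode)
    drug <- filter_drug_genes(clusters, input$ann, cfg$min_cluster_score)
    list(clusters = clusters, filtered_drug_genes = drug)
  })
  if (!is.null(out)) {
    utils::write.table(mcode_cluster_table(mcode_res$clusters),
                       file.path(out, "mcode_clusters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  # --- knockout --------------------------------------------------------
  traj <- in_stage("knockout", {
    run_knockout(net, tree, order = cfg$knockout_order,
                 rng_seed = cfg$rng_seed, n_boot = 0L,
                 thresholds = thresholds)
  })
  if (!is.null(out)) {
    utils::write.table(knockout_table(traj),
                       file.path(out, "knockout.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  # --- resultant network ----------------------------------------------
  rn <- in_stage("resultant", {
    if (length(kr_report$motif_localized_hubs) > 0L ||
        length(mcode_res$filtered_drug_genes) > 0L) {
      rn_net <- build_resultant_network(net,
                                        kr_report$motif_localized_hubs,
                                        mcode_res$filtered_drug_genes)
      list(network = rn_net,
           hubs = rank_rn_hubs(rn_net, cfg$cb_cutoff))
    } else {
      list(network = NULL, hubs = NULL)
    }
  })
  if (!is.null(out) && !is.null(rn$network)) {
    write_edge_list(rn$network, file.path(out, "resultant_network.tsv"))
    utils::write.table(rn$hubs, file.path(out, "resultant_hubs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- summary ---------------------------------------------------------
  summary <- list(
    n_nodes = igraph::vcount(net), n_edges = igraph::ecount(net),
    topology_class = topo$topology_class,
    assortative = topo$assortative,
    exponents = lapply(topo$fits, function(f) {
      if (is.null(f)) NULL else f$exponent
    }),
    hub_threshold = kr_report$hub_threshold,
    n_hubs = kr_report$n_hubs,
    n_motif_localized_hubs = length(kr_report$motif_localized_hubs),
    key_regulators = kr_report$key_regulators,
    hierarchy_depth = kr_report$max_depth,
    n_mcode_clusters = length(mcode_res$clusters),
    n_filtered_drug_genes = length(mcode_res$filtered_drug_genes),
    knockout_steps = length(traj$steps) - 1L,
    rn_nodes = if (is.null(rn$network)) 0L else igraph::vcount(rn$network),
    rn_edges = if (is.null(rn$network)) 0L else igraph::ecount(rn$network))
  if (!is.null(out)) {
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  invisible(list(network = net, annotations = input$ann, truth = truth,
                 topology = topo, tree = tree, kr_report = kr_report,
                 mcode = mcode_res, knockout = traj, resultant = rn,
                 summary = summary, config = cfg))
}

config_as_list <- function(cfg) {
  out <- unclass(cfg)
  out$mcode <- unclass(out$mcode)
  out
}

#' Resultant network of motif-localized hubs and filtered drug genes
#'
#' Induced subgraph of the source network on the union of the
#' motif-localized hubs and the noise-filtered drug-associated genes,
#' restricted to its largest connected component (members isolated within
#' the union are dropped with a message).
#'
#' @param net The source network.
#' @param motif_hubs Character vector of motif-localized hub ids.
#' @param drug_genes Character vector of filtered drug-gene ids.
#' @return The resultant network.
#' @export
build_resultant_network <- function(net, motif_hubs, drug_genes) {
  members <- union(motif_hubs, drug_genes)
  if (length(members) == 0L) stop("empty resultant network: no members")
  rn <- induced_network(net, members)
  comp <- igraph::components(rn)
  big <- which.max(comp$csize)
  dropped <- sum(comp$membership != big)
  if (dropped > 0L) {
    message("dropping ", dropped,
            " member(s) outside the largest component")
  }
  igraph::induced_subgraph(rn, igraph::V(rn)$name[comp$membership == big])
}

#' Rank resultant-network hubs by betweenness and degree
#'
#' Normalized betweenness is rounded to 3 decimal places before the
#' cutoff comparison; genes whose rounded value reaches `cb_cutoff` are
#' returned ordered by betweenness (descending), then degree
#' (descending), then id.
#'
#' @param rn A (non-empty) resultant network.
#' @param cb_cutoff Betweenness floor (default 0.010).
#' @return Data frame with columns `gene`, `degree`, `cb`.
#' @export
rank_rn_hubs <- function(rn, cb_cutoff = 0.010) {
  if (igraph::vcount(rn) == 0L) stop("empty network")
  cb <- round(as.numeric(betweenness_centrality(rn, normalized = TRUE)), 3L)
  deg <- igraph::degree(rn)
  d <- data.frame(gene = igraph::V(rn)$name, degree = as.integer(deg),
                  cb = cb)
  d <- d[d$cb >= cb_cutoff, , drop = FALSE]
  d <- d[order(-d$cb, -d$degree, d$gene), , drop = FALSE]
  rownames(d) <- NULL
  d
}
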