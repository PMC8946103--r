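#' Undirected interaction networks
#'
#' Networks are represented as simple undirected [igraph::igraph] graphs with
#' character vertex names (gene symbols or other opaque identifiers).
#' `as_network()` validates and coerces an igraph object or a two-column
#' edge table into this canonical form: self-loops and duplicated edges are
#' removed, every vertex carries a unique non-empty name, and node identifiers
#' are case-sensitive (no gene-symbol normalization is attempted).
#'
#' @param x An igraph graph, or a two-column character matrix/data.frame of
#'   edges. Additional columns are ignored.
#' @param name Optional label stored as the graph's `name` attribute.
#' @param isolates Optional character vector of extra node ids to include as
#'   degree-zero vertices.
#' @return A simple undirected named igraph graph.
#' @examples
#' net <- as_network(cbind(c("A", "B"), c("B", "C")))
#' network_size(net)
#' @export
as_network <- function(x, name = NULL, isolates = NULL) {
  if (igraph::is_igraph(x)) {
    g <- x
    if (igraph::is_directed(g)) {
      g <- igraph::as_undirected(g, mode = "collapse")
    }
    if (is.null(igraph::V(g)$name)) {
      igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    }
  } else {
    edges <- as.matrix(x)
    if (ncol(edges) < 2L) stop("edge table needs at least two columns")
    edges <- edges[, 1:2, drop = FALSE]
    storage.mode(edges) <- "character"
    ids <- unique(c(edges[, 1L], edges[, 2L], as.character(isolates)))
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges[, 1L], to = edges[, 2L],
                 stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = ids, stringsAsFactors = FALSE)
    )
  }
  n_loops <- sum(igraph::which_loop(g))
  n_multi <- sum(igraph::which_multiple(g))
  if (n_loops > 0L || n_multi > 0L) {
    message("dropped ", n_loops, " self-loop(s) and ", n_multi,
            " duplicate edge(s)")
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  }
  nm <- igraph::V(g)$name
  if (anyNA(nm) || any(!nzchar(nm))) stop("all node identifiers must be non-empty")
  if (anyDuplicated(nm)) stop("duplicate node identifiers")
  if (!is.null(name)) g$name <- name
  g
}

#' @describeIn as_network Number of nodes.
#' @export
network_size <- function(x) igraph::vcount(x)

#' @describeIn as_network Number of edges.
#' @export
network_edges <- function(x) igraph::ecount(x)

#' Read an interaction network from an edge-list file
#'
#' Accepts two-column delimited edge lists (a third weight column, if present,
#' is ignored) and SIF-style `node relation node [node ...]` lines via
#' `format = "sif"`. Lines starting with `#` are comments. Self-loops and
#' duplicate edges are dropped with a message stating the counts.
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter; `NULL` (default) splits on any
#'   whitespace, `"\t"` enforces tab-separated fields.
#' @param format `"edgelist"` (default) or `"sif"`.
#' @param name Optional network label; defaults to the file name.
#' @return A network (see [as_network()]).
#' @export
read_edge_list <- function(path, delimiter = NULL,
                           format = c("edgelist", "sif"), name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) stop("no edges in ", path)
  split_one <- function(line) {
    if (is.null(delimiter)) strsplit(trimws(line), "\\s+")[[1L]]
    else strsplit(line, delimiter, fixed = TRUE)[[1L]]
  }
  fields <- lapply(lines[idx], split_one)
  if (format == "sif") {
    # node [relation node [node ...]]; a 1-field line is a lone node
    edges <- do.call(rbind, lapply(fields, function(f) {
      if (length(f) < 3L) return(NULL)
      cbind(f[1L], f[3:length(f)])
    }))
    isolates <- unlist(lapply(fields, function(f) if (length(f) < 3L) f[1L]))
    if (is.null(edges)) stop("no edges in ", path)
  } else {
    bad <- which(vapply(fields, length, 1L) < 2L)
    if (length(bad) > 0L) {
      stop("malformed line ", idx[bad[1L]], " in ", path,
           ": expected at least 2 fields")
    }
    edges <- do.call(rbind, lapply(fields, function(f) f[1:2]))
    isolates <- NULL
  }
  as_network(edges, name = if (is.null(name)) basename(path) else name,
             isolates = isolates)
}

#' Write a network as a tab-separated edge list
#'
#' Isolated nodes are preserved as `# isolate:` comment lines so that a
#' write/read round trip reproduces the node set exactly.
#'
#' @param net A network.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  iso <- names(which(igraph::degree(net) == 0L))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(el) > 0L) {
    writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), con)
  }
  if (length(iso) > 0L) writeLines(paste0("# isolate:\t", iso), con)
  invisible(path)
}

#' Re-read an edge list written by [write_edge_list()]
#' @inheritParams read_edge_list
#' @keywords internal
#' @noRd
read_written_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  iso <- sub("^# isolate:\\t", "", grep("^# isolate:\t", lines, value = TRUE))
  net <- read_edge_list(path, delimiter = "\t")
  if (length(iso) > 0L) net <- igraph::add_vertices(net, length(iso), name = iso)
  net
}

#' Read node annotations (drug-associated gene flags)
#'
#' Expects a tab-separated table whose header contains a `node` column and a
#' `drug_associated` column with values in `true/false/1/0` (case
#' insensitive). Any further columns are preserved. Looking up a node absent
#' from the table must be treated as "unannotated", never as drug-associated;
#' [is_drug_associated()] implements that contract by returning `NA`.
#'
#' @param path Path to the TSV file.
#' @return A `node_annotations` data frame with columns `node`,
#'   `drug_associated` and any extra columns from the file.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("node", "drug_associated")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop("annotation table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  flag <- tolower(trimws(as.character(tab$drug_associated)))
  ok <- flag %in% c("true", "false", "1", "0")
  if (any(!ok)) {
    stop("invalid drug_associated value(s): ",
         paste(unique(flag[!ok]), collapse = ", "))
  }
  tab$node <- as.character(tab$node)
  if (anyDuplicated(tab$node)) stop("duplicate node rows in annotation table")
  tab$drug_associated <- flag %in% c("true", "1")
  class(tab) <- c("node_annotations", "data.frame")
  tab
}

#' Construct annotations in code
#'
#' @param node Character vector of node ids.
#' @param drug_associated Logical vector, recycled to `length(node)`.
#' @param ... Extra columns.
#' @return A `node_annotations` data frame.
#' @export
node_annotations <- function(node, drug_associated = FALSE, ...) {
  ann <- data.frame(node = as.character(node),
                    drug_associated = rep_len(drug_associated, length(node)),
                    ..., stringsAsFactors = FALSE)
  if (anyDuplicated(ann$node)) stop("duplicate node ids")
  class(ann) <- c("node_annotations", "data.frame")
  ann
}

#' @describeIn read_annotations Vectorized lookup: `TRUE`/`FALSE` for
#'   annotated nodes, `NA` for nodes absent from the table.
#' @param ann A `node_annotations` table.
#' @param nodes Character vector of node ids to look up.
#' @export
is_drug_associated <- function(ann, nodes) {
  out <- ann$drug_associated[match(nodes, ann$node)]
  names(out) <- nodes
  out
}

#' Write annotations as TSV
#' @param ann A `node_annotations` table.
#' @param path Output path.
#' @export
write_annotations <- function(ann, path) {
  out <- as.data.frame(ann)
  out$drug_associated <- ifelse(out$drug_associated, "true", "false")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Induced subgraph on a set of member nodes
#'
#' @param net A network.
#' @param members Non-empty character vector of node ids, all present in
#'   `net`.
#' @return The network on exactly `members` with every edge of `net` whose
#'   both endpoints are members.
#' @export
induced_network <- function(net, members) {
  members <- unique(as.character(members))
  if (length(members) == 0L) stop("members must be non-empty")
  absent <- setdiff(members, igraph::V(net)$name)
  if (length(absent) > 0L) {
    stop("members not in network: ", paste(absent, collapse = ", "))
  }
  igraph::induced_subgraph(net, members)
}

#' Remove nodes from a network (knockout primitive)
#'
#' Returns a new network without `victims` and without any edge touching
#' them. Nodes isolated by the removal are retained with degree zero; their
#' count is reported via a message and the `newly_isolated` attribute.
#'
#' @param net A network.
#' @param victims Character vector of node ids to remove (may be empty).
#' @param quiet Suppress the isolation message.
#' @return The reduced network, with attribute `newly_isolated`.
#' @export
remove_network_nodes <- function(net, victims, quiet = FALSE) {
  victims <- unique(as.character(victims))
  absent <- setdiff(victims, igraph::V(net)$name)
  if (length(absent) > 0L) {
    stop("victims not in network: ", paste(absent, collapse = ", "))
  }
  if (length(victims) == igraph::vcount(net)) {
    stop("empty result: refusing to remove every node")
  }
  iso_before <- sum(igraph::degree(net) == 0L)
  out <- igraph::delete_vertices(net, victims)
  newly_iso <- sum(igraph::degree(out) == 0L) -
    (iso_before - sum(igraph::degree(net)[victims] == 0L))
  if (!quiet && newly_iso > 0L) {
    message(newly_iso, " node(s) isolated by removal")
  }
  attr(out, "newly_isolated") <- newly_iso
  out
}
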