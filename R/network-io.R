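## Co-occurrence network container and Gephi-importable exports.

#' Construct a co-occurrence network
#'
#' A signed, simple, undirected graph. Nodes carry their feature rank,
#' phylum (for genus nodes) or node class, mean relative abundance and
#' degree; edges carry the Spearman rho, its p-value and the sign of rho.
#' Isolated nodes are not part of the network (every listed node has
#' degree >= 1).
#'
#' @param nodes data frame with at least \code{feature_id}; optional
#'   \code{rank}, \code{phylum}, \code{node_class}, \code{mean_abundance}.
#' @param edges data frame with columns \code{a}, \code{b}, \code{rho},
#'   \code{p}; \code{sign} is derived from \code{rho}.
#' @param mode \code{"taxa"} or \code{"taxa_gene"}.
#' @return A \code{co_network} object with components \code{nodes},
#'   \code{edges}, \code{mode}. Node degrees are (re)computed.
#' @export
co_network <- function(nodes, edges, mode = c("taxa", "taxa_gene")) {
  mode <- match.arg(mode)
  if (nrow(edges)) {
    assert_that(all(edges$a != edges$b), "self-loops are not allowed",
                class = "schema_error")
    key <- paste(pmin(edges$a, edges$b), pmax(edges$a, edges$b))
    assert_that(!anyDuplicated(key), "duplicate edges are not allowed",
                class = "schema_error")
    edges$sign <- ifelse(edges$rho >= 0, "+", "-")
    used <- unique(c(edges$a, edges$b))
    missing <- setdiff(used, nodes$feature_id)
    assert_that(length(missing) == 0L,
                paste("edges reference unknown nodes:",
                      paste(utils::head(missing, 3L), collapse = ", ")),
                class = "schema_error")
    nodes <- nodes[nodes$feature_id %in% used, , drop = FALSE]
    deg <- table(c(edges$a, edges$b))
    nodes$degree <- as.integer(deg[nodes$feature_id])
  } else {
    edges <- data.frame(a = character(), b = character(), rho = numeric(),
                        p = numeric(), sign = character(),
                        stringsAsFactors = FALSE)
    nodes <- nodes[0L, , drop = FALSE]
    if (nrow(nodes) == 0L && !"degree" %in% names(nodes)) nodes$degree <- integer()
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, mode = mode),
            class = "co_network")
}

#' @export
print.co_network <- function(x, ...) {
  cat("<co_network mode=", x$mode, "> ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges (",
      sum(x$edges$sign == "+"), " positive, ",
      sum(x$edges$sign == "-"), " negative)\n", sep = "")
  invisible(x)
}

#' Convert a co-occurrence network to an igraph graph
#'
#' Node and edge attributes are carried over; useful for layouts or
#' further graph analysis.
#'
#' @param network a \code{co_network}.
#' @return an \pkg{igraph} undirected graph.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "co_network"))
  nodes <- network$nodes
  names(nodes)[names(nodes) == "feature_id"] <- "name"
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = nodes)
}

.node_sidecar <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_nodes.tsv")
}

#' Export a co-occurrence network
#'
#' \code{graphml} writes a Gephi-importable GraphML file with all node and
#' edge attributes. \code{edge_list_tsv} writes the edge list at
#' \code{path} (rho and p in 6-decimal fixed format) and the node
#' attribute table in a sidecar file \code{<path minus ext>_nodes.tsv};
#' re-reading with [read_network_edges()] reproduces nodes, edges and
#' attributes exactly at that precision.
#'
#' @param network a \code{co_network}.
#' @param path output file path.
#' @param format \code{"graphml"} or \code{"edge_list_tsv"}.
#' @return invisibly, \code{path}.
#' @export
write_network <- function(network, path, format = c("graphml", "edge_list_tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "co_network"))
  if (nrow(network$edges) == 0L) warn2("writing an empty network: ", path)
  if (format == "graphml") {
    if (nrow(network$edges) == 0L) {
      ## igraph GraphML of an empty graph: write header-only file directly
      writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
                   '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
                   '<graph edgedefault="undirected"/>', '</graphml>'), path)
    } else {
      igraph::write_graph(as_igraph(network), path, format = "graphml")
    }
  } else {
    e <- network$edges
    e$rho <- sprintf("%.6f", e$rho)
    e$p <- sprintf("%.6f", e$p)
    utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
    n <- network$nodes
    if (nrow(n) && "mean_abundance" %in% names(n))
      n$mean_abundance <- sprintf("%.6g", n$mean_abundance)
    utils::write.table(n, .node_sidecar(path), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Re-read an exported edge-list network
#'
#' Reads the TSV pair written by
#' \code{write_network(..., format = "edge_list_tsv")}.
#'
#' @param path the edge-list TSV path.
#' @param mode network mode to declare (\code{"taxa"} or
#'   \code{"taxa_gene"}).
#' @return a \code{co_network}.
#' @export
read_network_edges <- function(path, mode = "taxa") {
  e <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(a = "character", b = "character"))
  npath <- .node_sidecar(path)
  n <- if (file.exists(npath))
    utils::read.delim(npath, stringsAsFactors = FALSE,
                      colClasses = c(feature_id = "character"))
  else
    data.frame(feature_id = unique(c(e$a, e$b)), stringsAsFactors = FALSE)
  if (nrow(n) && "mean_abundance" %in% names(n))
    n$mean_abundance <- as.numeric(n$mean_abundance)
  co_network(n, e, mode = mode)
}
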