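## Thresholded-Spearman co-occurrence networks: genus-genus networks over
## the most abundant genera and taxa-vs-functional-gene networks over the
## dominant phyla and the 12 C/N-cycle marker genes, plus the topological
## index vector and hub detection.

#' Network construction specification
#'
#' Thresholds and candidate selection for co-occurrence networks. The
#' defaults follow the two standard configurations: genus-genus networks
#' use the top 300 genera at \eqn{|\rho| > 0.9}, taxa-gene networks the
#' top 30 phyla plus the C/N marker genes at \eqn{|\rho| > 0.6}, both at
#' p < 0.05 with no multiple-testing correction (a Benjamini-Hochberg
#' option is available).
#'
#' @param mode \code{"taxa"} or \code{"taxa_gene"}.
#' @param top_k candidate features by mean relative abundance (default 300
#'   for taxa mode, 30 for taxa_gene mode).
#' @param rho_threshold correlation magnitude threshold (strict >).
#' @param p_threshold significance threshold (strict <).
#' @param use_absolute_rho threshold on \eqn{|\rho|} (default). Networks
#'   report negative edges, so the magnitude reading is the default; set
#'   \code{FALSE} for the strict signed reading \eqn{\rho > } threshold.
#' @param treatment optional treatment label; when given (with a design)
#'   only that treatment's samples enter correlation, pooling all days and
#'   replicates.
#' @param p_adjust \code{"none"} (default) or any \code{stats::p.adjust}
#'   method applied to the upper-triangle p-values before thresholding.
#' @param p_method forwarded to [spearman_matrix()].
#' @return a \code{network_spec} list.
#' @export
network_spec <- function(mode = c("taxa", "taxa_gene"),
                         top_k = NULL,
                         rho_threshold = NULL,
                         p_threshold = 0.05,
                         use_absolute_rho = TRUE,
                         treatment = NULL,
                         p_adjust = "none",
                         p_method = "t_approx") {
  mode <- match.arg(mode)
  top_k <- top_k %||% if (mode == "taxa") 300L else 30L
  rho_threshold <- rho_threshold %||% if (mode == "taxa") 0.9 else 0.6
  assert_that(rho_threshold > 0 && rho_threshold < 1,
              "rho_threshold must be in (0,1)", class = "config_error")
  assert_that(p_threshold > 0 && p_threshold <= 1,
              "p_threshold must be in (0,1]", class = "config_error")
  structure(list(mode = mode, top_k = as.integer(top_k),
                 rho_threshold = rho_threshold, p_threshold = p_threshold,
                 use_absolute_rho = use_absolute_rho, treatment = treatment,
                 p_adjust = p_adjust, p_method = p_method),
            class = "network_spec")
}

.select_samples <- function(table, design, spec) {
  samples <- colnames(table$matrix)
  if (!is.null(spec$treatment)) {
    assert_that(!is.null(design), "a sample design is needed to select by treatment",
                class = "config_error")
    keep <- design$sample_id[design$treatment == spec$treatment]
    samples <- intersect(samples, keep)
  }
  assert_that(length(samples) >= 4L, "fewer than 4 samples selected")
  samples
}

.threshold_edges <- function(cr, spec) {
  rho <- cr$rho
  p <- cr$p
  if (spec$p_adjust != "none") {
    ut <- upper.tri(p)
    p[ut] <- stats::p.adjust(p[ut], method = spec$p_adjust)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  strength <- if (spec$use_absolute_rho) abs(rho) else rho
  keep <- strength > spec$rho_threshold & p < spec$p_threshold
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  data.frame(a = rownames(rho)[idx[, 1L]], b = colnames(rho)[idx[, 2L]],
             rho = rho[idx], p = p[idx], stringsAsFactors = FALSE)
}

#' Build a genus-genus co-occurrence network
#'
#' Selects the \code{top_k} candidate features by mean relative abundance
#' over the selected samples, computes the Spearman matrix over those
#' samples, keeps edges passing the \eqn{|\rho|} and p thresholds and
#' drops isolated nodes. An empty network (no surviving edge) is returned
#' with a warning, not an error.
#'
#' @param table feature \code{abundance_table} (genus or phylum).
#' @param spec a [network_spec()].
#' @param design optional \code{sample_design}, required when
#'   \code{spec$treatment} is set.
#' @return a \code{co_network} with node attributes \code{rank},
#'   \code{phylum} (from the table's feature-parent map, if any) and
#'   \code{mean_abundance}.
#' @export
build_network <- function(table, spec = network_spec("taxa"), design = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  samples <- .select_samples(table, design, spec)
  rel <- relative_abundance(table)
  cand <- suppressWarnings(
    top_k_features(rel, k = min(spec$top_k, nrow(rel$matrix)),
                   samples = samples))
  assert_that(nrow(cand$matrix) >= 2L, "need at least 2 candidate features")
  X <- cand$matrix[, samples, drop = FALSE]
  cr <- spearman_matrix(X, p_method = spec$p_method)
  edges <- .threshold_edges(cr, spec)
  if (nrow(edges) == 0L) warn2("no edge passed the thresholds; empty network")
  pmap <- table$feature_parent
  nodes <- data.frame(
    feature_id = rownames(X),
    rank = table$rank,
    phylum = if (!is.null(pmap)) unname(pmap[rownames(X)]) else NA_character_,
    mean_abundance = rowMeans(X),
    stringsAsFactors = FALSE
  )
  co_network(nodes, edges, mode = "taxa")
}

#' Build a taxa-vs-functional-gene network
#'
#' Candidates are the \code{top_k} (default 30) most abundant phyla plus
#' the 12 C/N-cycle marker genes present in the gene table (absent
#' markers are listed in a warning and skipped). Edges among all candidate
#' pairs — phylum-phylum, gene-gene, and phylum-gene — are kept at the
#' taxa-gene thresholds (default \eqn{|\rho| > 0.6}, p < 0.05).
#'
#' @param phylum_table phylum \code{abundance_table}.
#' @param gene_table gene \code{abundance_table}.
#' @param spec a [network_spec()] (mode \code{"taxa_gene"}).
#' @param design optional \code{sample_design} for treatment selection.
#' @param genes marker gene ids to include (default [cn_cycle_genes()]).
#' @return a \code{co_network} with node attribute \code{node_class}
#'   (\code{"phylum"}/\code{"gene"}) and, as attribute
#'   \code{"gene_phylum_counts"}, the number of phyla attached to each
#'   gene.
#' @export
build_taxa_gene_network <- function(phylum_table, gene_table,
                                    spec = network_spec("taxa_gene"),
                                    design = NULL,
                                    genes = unlist(cn_cycle_genes(),
                                                   use.names = FALSE)) {
  stopifnot(inherits(phylum_table, "abundance_table"),
            inherits(gene_table, "abundance_table"))
  samples <- intersect(colnames(phylum_table$matrix),
                       colnames(gene_table$matrix))
  ptab <- abundance_table(phylum_table$matrix[, samples, drop = FALSE],
                          rank = phylum_table$rank)
  samples <- .select_samples(ptab, design, spec)

  missing <- setdiff(genes, rownames(gene_table$matrix))
  if (length(missing))
    warn2("gene table lacks marker gene(s): ", paste(missing, collapse = ", "))
  genes <- setdiff(genes, missing)
  assert_that(length(genes) >= 1L, "no marker genes present in the gene table")

  rel <- relative_abundance(ptab)
  topp <- suppressWarnings(
    top_k_features(rel, k = min(spec$top_k, nrow(rel$matrix)),
                   samples = samples))
  P <- topp$matrix[, samples, drop = FALSE]
  G <- gene_table$matrix[genes, samples, drop = FALSE]
  X <- rbind(P, G)
  cr <- spearman_matrix(X, p_method = spec$p_method)
  edges <- .threshold_edges(cr, spec)
  if (nrow(edges) == 0L) warn2("no edge passed the thresholds; empty network")
  nodes <- data.frame(
    feature_id = rownames(X),
    rank = c(rep(topp$rank, nrow(P)), rep("gene", nrow(G))),
    node_class = c(rep("phylum", nrow(P)), rep("gene", nrow(G))),
    mean_abundance = rowMeans(X),
    stringsAsFactors = FALSE
  )
  net <- co_network(nodes, edges, mode = "taxa_gene")
  cls <- stats::setNames(nodes$node_class, nodes$feature_id)
  cross <- net$edges[xor(cls[net$edges$a] == "gene",
                         cls[net$edges$b] == "gene"), , drop = FALSE]
  gene_end <- ifelse(cls[cross$a] == "gene", cross$a, cross$b)
  attr(net, "gene_phylum_counts") <-
    stats::setNames(as.integer(table(factor(gene_end, levels = genes))), genes)
  net
}

#' Topological indices of a co-occurrence network
#'
#' The standard index vector for reporting co-occurrence networks: node
#' and edge counts, positive/negative edge ratio (percent), network
#' diameter (longest geodesic within the largest connected component),
#' average path length (mean geodesic over all connected node pairs,
#' unordered, unit edge lengths; pairs in different components are
#' excluded, as Gephi does) and average degree \eqn{2E/N}.
#'
#' @param network a \code{co_network}.
#' @return a one-row data frame of class \code{network_topology} with
#'   columns \code{n_nodes}, \code{n_edges}, \code{pos_ratio_pct},
#'   \code{neg_ratio_pct}, \code{diameter}, \code{avg_path_length},
#'   \code{avg_degree}; all \code{NA} for an empty network.
#' @export
topology <- function(network) {
  stopifnot(inherits(network, "co_network"))
  if (nrow(network$edges) == 0L) {
    out <- data.frame(n_nodes = NA_integer_, n_edges = NA_integer_,
                      pos_ratio_pct = NA_real_, neg_ratio_pct = NA_real_,
                      diameter = NA_real_, avg_path_length = NA_real_,
                      avg_degree = NA_real_)
    class(out) <- c("network_topology", "data.frame")
    return(out)
  }
  g <- as_igraph(network)
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  d <- igraph::distances(g, weights = NA)
  finite <- d[upper.tri(d)][is.finite(d[upper.tri(d)])]
  comps <- igraph::components(g)
  big <- which.max(comps$csize)
  sub <- igraph::induced_subgraph(g, which(comps$membership == big))
  pos <- sum(network$edges$sign == "+")
  out <- data.frame(
    n_nodes = n,
    n_edges = e,
    pos_ratio_pct = 100 * pos / e,
    neg_ratio_pct = 100 * (e - pos) / e,
    diameter = igraph::diameter(sub, weights = NA),
    avg_path_length = mean(finite),
    avg_degree = 2 * e / n
  )
  class(out) <- c("network_topology", "data.frame")
  out
}

#' High-connectivity (hub) nodes
#'
#' Returns the nodes whose degree reaches the given quantile of the
#' network's degree distribution; ties are included, so a regular graph
#' returns every node.
#'
#' @param network a nonempty \code{co_network}.
#' @param quantile degree quantile (default 0.95).
#' @return data frame of hub nodes (subset of \code{network$nodes}),
#'   ordered by decreasing degree.
#' @export
hub_nodes <- function(network, quantile = 0.95) {
  stopifnot(inherits(network, "co_network"))
  assert_that(nrow(network$nodes) > 0L, "empty network has no hubs")
  thr <- stats::quantile(network$nodes$degree, probs = quantile, names = FALSE)
  hubs <- network$nodes[network$nodes$degree >= thr, , drop = FALSE]
  hubs[order(-hubs$degree, hubs$feature_id), , drop = FALSE]
}
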