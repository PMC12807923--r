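## End-to-end orchestration: synth -> biolog -> diversity -> network ->
## compare, driven by one config, producing a flat directory of plain
## TSV/GraphML outputs so every stage is independently diffable.

#' Default pipeline configuration
#'
#' Every threshold of the pipeline as a config key with its standard value
#' as default; any subset can be overridden in a YAML file or list passed
#' to [run_pipeline()].
#'
#' @return nested list: \code{seed}, \code{synth} (\code{enabled} plus
#'   [synth_config()] overrides), \code{input} (file paths used when synth
#'   is disabled), \code{stages} (logical toggles), \code{thresholds}.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    synth = list(enabled = TRUE),
    input = list(plates = NULL, genus = NULL, phylum = NULL, genes = NULL,
                 metadata = NULL),
    stages = list(biolog = TRUE, diversity = TRUE, network = TRUE,
                  compare = TRUE),
    thresholds = list(taxa_rho = 0.9, taxa_gene_rho = 0.6, p = 0.05,
                      top_k_genus = 300L, top_k_phylum = 30L,
                      read_time_h = 96, alpha = 0.05, hub_quantile = 0.95)
  )
}

.load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  utils::modifyList(default_run_config(), config %||% list())
}

.config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(cfg), f)
  unname(tools::md5sum(f))
}

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) the study data, then runs the enabled stages:
#' EcoPlate profiling (AWCD time series, functional diversity indices,
#' 96-h substrate profile), community diversity (alpha table, Bray-Curtis
#' matrix, PCoA and PCA scores), per-treatment co-occurrence networks
#' (taxa and taxa-gene GraphML + edge lists, topology and hub tables),
#' and per-timepoint treatment comparisons with compact letters for the
#' C/N marker genes and EcoPlate indices. A \code{manifest.yaml} records
#' the seed, config hash and completed stages; on a stage failure the
#' manifest retains the stages already finished and the error propagates.
#'
#' @param config a YAML file path or nested list (see
#'   [default_run_config()]); missing keys take defaults.
#' @param out_dir output directory (created).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- .load_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, config_hash = .config_hash(cfg),
                   stages_done = character())
  save_manifest <- function() {
    writeLines(yaml::as.yaml(manifest), file.path(out_dir, "manifest.yaml"))
  }
  on.exit(save_manifest())

  ## -- data -----------------------------------------------------------
  if (isTRUE(cfg$synth$enabled)) {
    sargs <- cfg$synth
    sargs$enabled <- NULL
    sargs$seed <- sargs$seed %||% cfg$seed
    scfg <- do.call(synth_config, sargs)
    study <- generate_synthetic_study(scfg)
    write_synthetic_study(study, file.path(out_dir, "synth"))
  } else {
    inp <- cfg$input
    design <- read_sample_design(inp$metadata)
    study <- list(
      design = design,
      plates = if (!is.null(inp$plates)) read_plate_readings(inp$plates),
      genus = if (!is.null(inp$genus)) read_abundance_table(inp$genus, "genus"),
      phylum = if (!is.null(inp$phylum))
        read_abundance_table(inp$phylum, "phylum"),
      genes = if (!is.null(inp$genes)) read_abundance_table(inp$genes, "gene")
    )
  }
  manifest$stages_done <- c(manifest$stages_done, "data")
  thr <- cfg$thresholds
  treatments <- unique(study$design$treatment)

  ## -- biolog ---------------------------------------------------------
  if (isTRUE(cfg$stages$biolog) && !is.null(study$plates)) {
    prof <- blank_correct(study$plates, time_h = thr$read_time_h)
    .write_tsv(awcd_timeseries(study$plates),
               file.path(out_dir, "awcd_timeseries.tsv"))
    idx <- functional_diversity(prof)
    idx$AWCD <- unname(awcd(prof)[idx$sample_id])
    .write_tsv(idx, file.path(out_dir, "biolog_indices.tsv"))
    .write_tsv(data.frame(substrate = colnames(prof$activity),
                          t(prof$activity), check.names = FALSE),
               file.path(out_dir, sprintf("profile_%dh.tsv", thr$read_time_h)))
    manifest$stages_done <- c(manifest$stages_done, "biolog")
  }

  ## -- diversity ------------------------------------------------------
  if (isTRUE(cfg$stages$diversity) && !is.null(study$genus)) {
    .write_tsv(alpha_diversity(study$genus), file.path(out_dir, "alpha.tsv"))
    bc <- bray_curtis(relative_abundance(study$genus))
    .write_tsv(data.frame(sample_id = rownames(bc), bc, check.names = FALSE),
               file.path(out_dir, "bray_curtis.tsv"))
    ord <- pcoa(bc, n_axes = 2)
    sc <- data.frame(sample_id = rownames(ord$scores), ord$scores,
                     check.names = FALSE)
    attr(sc, "percent_explained") <- ord$percent_explained
    .write_tsv(sc, file.path(out_dir, "pcoa_scores.tsv"))
    ordp <- pca_euclidean(relative_abundance(study$genus), n_axes = 2)
    .write_tsv(data.frame(sample_id = rownames(ordp$scores), ordp$scores,
                          check.names = FALSE),
               file.path(out_dir, "pca_scores.tsv"))
    manifest$stages_done <- c(manifest$stages_done, "diversity")
  }

  ## -- networks -------------------------------------------------------
  if (isTRUE(cfg$stages$network) && !is.null(study$genus)) {
    topo_rows <- list()
    for (tr in treatments) {
      sp <- network_spec("taxa", top_k = thr$top_k_genus,
                         rho_threshold = thr$taxa_rho, p_threshold = thr$p,
                         treatment = tr)
      net <- suppressWarnings(build_network(study$genus, sp, study$design))
      write_network(net, file.path(out_dir, sprintf("network_taxa_%s.graphml", tr)))
      write_network(net, file.path(out_dir, sprintf("network_taxa_%s.tsv", tr)),
                    format = "edge_list_tsv")
      tp <- topology(net)
      topo_rows[[length(topo_rows) + 1L]] <-
        cbind(data.frame(mode = "taxa", treatment = tr), tp)
      if (nrow(net$nodes))
        .write_tsv(hub_nodes(net, thr$hub_quantile),
                   file.path(out_dir, sprintf("hubs_%s.tsv", tr)))
      if (!is.null(study$phylum) && !is.null(study$genes)) {
        spg <- network_spec("taxa_gene", top_k = thr$top_k_phylum,
                            rho_threshold = thr$taxa_gene_rho,
                            p_threshold = thr$p, treatment = tr)
        netg <- suppressWarnings(
          build_taxa_gene_network(study$phylum, study$genes, spg, study$design))
        write_network(netg,
                      file.path(out_dir, sprintf("network_taxa_gene_%s.graphml", tr)))
        write_network(netg,
                      file.path(out_dir, sprintf("network_taxa_gene_%s.tsv", tr)),
                      format = "edge_list_tsv")
        topo_rows[[length(topo_rows) + 1L]] <-
          cbind(data.frame(mode = "taxa_gene", treatment = tr), topology(netg))
      }
    }
    .write_tsv(do.call(rbind, topo_rows), file.path(out_dir, "topology.tsv"))
    manifest$stages_done <- c(manifest$stages_done, "network")
  }

  ## -- compare --------------------------------------------------------
  if (isTRUE(cfg$stages$compare) && !is.null(study$genes)) {
    letters_tab <- compare_by_timepoint(study$genes, study$design,
                                        alpha = thr$alpha)
    .write_tsv(letters_tab, file.path(out_dir, "gene_letters.tsv"))
    if (!is.null(study$plates)) {
      prof <- blank_correct(study$plates, time_h = thr$read_time_h)
      idx <- functional_diversity(prof)
      idx$AWCD <- unname(awcd(prof)[idx$sample_id])
      resp <- t(as.matrix(idx[, c("AWCD", "H_prime", "D_simpson", "U_mcintosh")]))
      colnames(resp) <- idx$sample_id
      .write_tsv(compare_by_timepoint(abundance_table(resp, rank = "gene"),
                                      study$design, alpha = thr$alpha),
                 file.path(out_dir, "biolog_letters.tsv"))
    }
    manifest$stages_done <- c(manifest$stages_done, "compare")
  }
  save_manifest()
  invisible(manifest)
}
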