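## Seeded synthetic-data generator emulating a 3-treatment x 3-replicate x
## 7-day soil microbiome study: EcoPlate kinetics, compositional genus and
## phylum tables with planted correlated blocks and treatment-by-time
## responders, and C/N-cycle gene tables coupled to the taxa through a
## known loading matrix. A ground-truth record accompanies every draw so
## that network-recovery and comparison machinery can be benchmarked.

## Deterministic per-artifact substreams: each output is drawn under its
## own seed derived from (master seed, artifact name), so adding a new
## artifact never perturbs existing ones.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131L)
  (as.integer(seed) %% 1000003L) * 2017L + (h %% 104729L)
}

with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

.default_plate_K <- function() {
  subs <- eco_substrates()$substrate
  K <- stats::setNames(rep(150, length(subs)), subs)
  high <- c("N-Acetyl-D-Glucosamine", "Tween 40", "Tween 80", "L-Arginine",
            "D-Galacturonic Acid", "L-Asparagine", "L-Serine", "D-Mannitol")
  low <- c("alpha-Cyclodextrin", "Glycogen", "D-Xylose", "Phenylethyl-amine",
           "L-Phenylalanine", "L-Threonine", "Glycyl-L-Glutamic Acid",
           "i-Erythritol")
  K[high] <- 240
  K[low] <- 60
  K[c("2-Hydroxy Benzoic Acid", "alpha-Ketobutyric Acid")] <- 0
  K
}

#' Synthetic-study configuration
#'
#' Bundles every tunable of the generator. The defaults emulate the study
#' design the package targets: treatments CK/T1/T5 (0, 180, 900 g a.i.
#' ha\eqn{^{-1}}), 3 replicates, sampling days 0/1/5/10/20/30/60 (63
#' samples), 300 genera on a power-law rank-abundance curve, three planted
#' 5-genus blocks with within-block copula correlation 0.95, one abundant
#' responder genus elevated tenfold in T5 after application, 18 functional
#' gene aggregates (12 C/N marker genes + 6 CAZy families) loading on
#' known genera, and logistic EcoPlate color kinetics with two
#' never-metabolized substrates and treatment-scaled activity.
#'
#' @param treatments named numeric vector of doses (g a.i. ha^-1), names
#'   are treatment labels.
#' @param n_replicates replicates per treatment/day.
#' @param days integer sampling days; day 0 is pre-treatment.
#' @param n_genera number of genus features.
#' @param rank_exponent s > 0; base log-abundance is \eqn{-s \log(rank)}.
#' @param blocks list of \code{list(ranks =, rho =)}: genus ranks forming a
#'   correlated block and the within-block latent (copula) correlation.
#' @param responders list of \code{list(genus =, treatment =, days =, fold =)};
#'   \code{days} is an inclusive range \code{c(from, to)}. Day-0 samples
#'   never receive responder effects (pre-treatment).
#' @param sigma_taxa latent log-scale noise sd for taxa; this single scale
#'   both disperses samples and carries the planted block correlation.
#' @param sigma_gene multiplicative lognormal noise sd for gene tables.
#' @param gene_loadings genes x genera loading matrix (sparse,
#'   nonnegative); \code{NULL} uses a default where each of the 18 genes
#'   loads on a distinct abundant genus (1.0 primary + 0.3 secondary).
#' @param plate list of plate-kinetics parameters: \code{K} (named
#'   per-substrate asymptote, OmniLog units), \code{r} (logistic rate,
#'   1/h), \code{t0} (midpoint, h), \code{sigma} (Gaussian read noise sd),
#'   \code{times} (read grid, h; must include 96), \code{activity} (named
#'   per-treatment activity multiplier).
#' @param seed master integer seed.
#' @return a \code{synth_config} list.
#' @export
synth_config <- function(treatments = c(CK = 0, T1 = 180, T5 = 900),
                         n_replicates = 3,
                         days = c(0, 1, 5, 10, 20, 30, 60),
                         n_genera = 300,
                         rank_exponent = 1,
                         blocks = list(
                           list(ranks = 11:15, rho = 0.95),
                           list(ranks = 16:20, rho = 0.95),
                           list(ranks = 21:25, rho = 0.95)
                         ),
                         responders = list(
                           list(genus = "g005", treatment = "T5",
                                days = c(1, 60), fold = 10)
                         ),
                         sigma_taxa = 0.5,
                         sigma_gene = 0.2,
                         gene_loadings = NULL,
                         plate = list(),
                         seed = 1) {
  plate_defaults <- list(K = .default_plate_K(), r = 0.1, t0 = 36, sigma = 4,
                         times = c(0, 24, 48, 72, 96),
                         activity = c(CK = 1, T1 = 0.9, T5 = 0.75))
  plate <- utils::modifyList(plate_defaults, plate)
  cfg <- list(treatments = treatments, n_replicates = as.integer(n_replicates),
              days = as.integer(days), n_genera = as.integer(n_genera),
              rank_exponent = rank_exponent, blocks = blocks,
              responders = responders, sigma_taxa = sigma_taxa,
              sigma_gene = sigma_gene, gene_loadings = gene_loadings,
              plate = plate, seed = as.integer(seed))
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  assert_that(cfg$n_genera >= 1L, "n_genera must be >= 1", class = "config_error")
  assert_that(cfg$rank_exponent > 0, "rank_exponent must be > 0",
              class = "config_error")
  assert_that(cfg$sigma_taxa >= 0 && cfg$sigma_gene >= 0,
              "noise sds must be >= 0", class = "config_error")
  used <- integer()
  for (b in cfg$blocks) {
    assert_that(b$rho > 0 && b$rho < 1, "within_block_rho must be in (0,1)",
                class = "config_error")
    if (any(b$ranks > cfg$n_genera) || any(b$ranks < 1L))
      stop2("block ranks exceed n_genera", class = "config_error")
    if (any(b$ranks %in% used))
      stop2("blocks must not overlap", class = "config_error")
    used <- c(used, b$ranks)
  }
  for (r in cfg$responders)
    assert_that(r$fold > 0, "responder fold-change must be > 0",
                class = "config_error")
  assert_that(96 %in% cfg$plate$times, "plate time grid must include 96 h",
              class = "config_error")
  structure(cfg, class = "synth_config")
}

genus_ids <- function(n) sprintf("g%03d", seq_len(n))

## Deterministic genus -> phylum map: 30 phyla, assignment cycle weighted
## so the first 8 phyla are dominant (they receive the most and the most
## abundant genera, mirroring an 8-dominant-phyla community).
genus_phylum_map <- function(n_genera) {
  cycle <- c(1:8, 9:19, 1:8, 20:30, 1:8, 1:8)  # length 54; phyla 1-8 x4
  idx <- cycle[((seq_len(n_genera) - 1L) %% length(cycle)) + 1L]
  stats::setNames(sprintf("p%02d", idx), genus_ids(n_genera))
}

#' Generate the sample design
#'
#' Full crossing of treatments, sampling days and replicates, with
#' deterministic sample ids \code{"<treatment>_d<day>_r<rep>"}. The
#' default configuration yields the emulated study's 63 samples
#' (3 treatments x 3 replicates x 7 days).
#'
#' @param cfg a [synth_config()].
#' @return a \code{sample_design}.
#' @export
generate_design <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  g <- expand.grid(replicate = seq_len(cfg$n_replicates), day = cfg$days,
                   treatment = names(cfg$treatments), stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  sample_design(
    sample_id = sprintf("%s_d%d_r%d", g$treatment, g$day, g$replicate),
    treatment = g$treatment, day = g$day, replicate = g$replicate,
    dose = unname(cfg$treatments[g$treatment])
  )
}

## Latent Gaussian draw with block-diagonal correlation: block members get
## sqrt(rho) * shared + sqrt(1-rho) * own, giving exact pairwise latent
## correlation rho inside each block and 0 elsewhere.
.draw_latent <- function(n_genera, n_samples, blocks) {
  z <- matrix(stats::rnorm(n_genera * n_samples), n_genera, n_samples)
  for (b in blocks) {
    shared <- stats::rnorm(n_samples)
    z[b$ranks, ] <- sqrt(b$rho) * matrix(shared, length(b$ranks), n_samples,
                                         byrow = TRUE) +
      sqrt(1 - b$rho) * z[b$ranks, , drop = FALSE]
  }
  z
}

#' Generate genus and phylum abundance tables with ground truth
#'
#' Genus log-abundances follow a power-law rank-abundance baseline
#' \eqn{\mu_g = -s \log(rank_g)}; a per-sample latent Gaussian vector with
#' block-diagonal correlation (a Gaussian copula: Spearman correlation is
#' invariant to the exponentiation, so planted rank correlation survives)
#' is scaled by \code{sigma_taxa} and exponentiated; responder fold
#' changes are applied multiplicatively to matching (treatment, day > 0)
#' samples; each column is then closed to relative abundances. The phylum
#' table aggregates member genera through a fixed genus-to-phylum map (30
#' phyla, 8 dominant).
#'
#' @param cfg a [synth_config()].
#' @param design a \code{sample_design} (>= 4 samples).
#' @return list with components \code{genus} and \code{phylum} (relative
#'   \code{abundance_table}s) and \code{truth} (planted edge pairs,
#'   responder spec, loading matrix used for gene generation).
#' @export
generate_taxon_table <- function(cfg, design) {
  stopifnot(inherits(cfg, "synth_config"))
  assert_that(nrow(design) >= 4L, "need at least 4 samples")
  n <- cfg$n_genera
  ids <- genus_ids(n)
  mu <- -cfg$rank_exponent * log(seq_len(n))

  z <- with_seed(substream_seed(cfg$seed, "taxa"),
                 .draw_latent(n, nrow(design), cfg$blocks))
  x <- exp(mu + cfg$sigma_taxa * z)
  dimnames(x) <- list(ids, design$sample_id)

  for (r in cfg$responders) {
    hit <- design$treatment == r$treatment & design$day > 0L &
      design$day >= r$days[1L] & design$day <= r$days[2L]
    x[r$genus, hit] <- x[r$genus, hit] * r$fold
  }
  x <- sweep(x, 2L, colSums(x), "/")

  pmap <- genus_phylum_map(n)
  ph <- rowsum(x, group = pmap[ids])
  genus_tab <- abundance_table(x, rank = "genus", is_relative = TRUE,
                               feature_parent = pmap)
  phylum_tab <- abundance_table(ph, rank = "phylum", is_relative = TRUE)

  planted <- do.call(rbind, lapply(cfg$blocks, function(b) {
    p <- t(utils::combn(ids[b$ranks], 2L))
    data.frame(a = p[, 1L], b = p[, 2L], rho = b$rho,
               stringsAsFactors = FALSE)
  }))
  if (is.null(planted))
    planted <- data.frame(a = character(), b = character(), rho = numeric())

  truth <- list(planted_edges = planted, responders = cfg$responders,
                loadings = default_gene_loadings(cfg))

  ## sanity check on planted dependence, meaningful only at decent n
  if (nrow(design) >= 20L && nrow(planted) > 0L) {
    rho <- stats::cor(t(x), method = "spearman")
    within <- mean(abs(rho[cbind(planted$a, planted$b)]))
    free <- setdiff(ids[1:min(40L, n)], unique(c(planted$a, planted$b)))
    if (length(free) >= 2L) {
      off <- abs(rho[free, free])
      between <- mean(off[upper.tri(off)])
      if (within <= between)
        warn2("planted blocks are not separable from background correlation")
    }
  }
  list(genus = genus_tab, phylum = phylum_tab, truth = truth)
}

#' Default gene loading matrix
#'
#' 18 rows (12 C/N marker genes then the 6 CAZy family aggregates) by
#' \code{n_genera} columns. Gene k loads 1.0 on the rank-k genus and 0.3
#' on the rank-(k+20) genus, so each gene tracks one distinct abundant
#' genus (and hence that genus's phylum aggregate).
#'
#' @param cfg a [synth_config()].
#' @return numeric matrix with gene rownames and genus colnames.
#' @export
default_gene_loadings <- function(cfg) {
  if (!is.null(cfg$gene_loadings)) return(cfg$gene_loadings)
  genes <- c(unlist(cn_cycle_genes(), use.names = FALSE), cazy_families())
  n <- cfg$n_genera
  L <- matrix(0, length(genes), n, dimnames = list(genes, genus_ids(n)))
  for (k in seq_along(genes)) {
    L[k, min(k, n)] <- 1
    if (k + 20L <= n) L[k, k + 20L] <- 0.3
  }
  L
}

#' Generate a functional-gene abundance table
#'
#' Gene abundance per sample is the loading-weighted sum of genus relative
#' abundances times multiplicative lognormal noise:
#' \eqn{g_s = (L x_s) \exp(\sigma_{gene} \epsilon)}. Gene ids are the 12
#' C/N-cycle markers plus the 6 CAZy family aggregates.
#'
#' @param cfg a [synth_config()].
#' @param genus_table genus \code{abundance_table} from
#'   [generate_taxon_table()].
#' @return an \code{abundance_table} with rank \code{"gene"} (18 rows).
#' @export
generate_gene_table <- function(cfg, genus_table) {
  stopifnot(inherits(cfg, "synth_config"))
  L <- default_gene_loadings(cfg)
  if (ncol(L) != nrow(genus_table$matrix) ||
      !all(colnames(L) == rownames(genus_table$matrix)))
    stop2("gene loading matrix columns do not align with genus ids",
          class = "config_error")
  base <- L %*% genus_table$matrix
  eps <- with_seed(substream_seed(cfg$seed, "genes"),
                   matrix(stats::rnorm(length(base)), nrow(base), ncol(base)))
  m <- base * exp(cfg$sigma_gene * eps)
  dimnames(m) <- list(rownames(L), colnames(genus_table$matrix))
  abundance_table(m, rank = "gene")
}

#' Generate EcoPlate reading time series
#'
#' Per-well signal follows logistic color development
#' \eqn{K_{sub} m_{treat} / (1 + e^{-r (t - t_0)})} plus truncated
#' Gaussian read noise; the two null substrates (2-Hydroxy Benzoic Acid,
#' alpha-Ketobutyric Acid) have K = 0, emulating carbon sources the soil
#' community cannot metabolize; the blank (Water) well is pure noise.
#' Treatment multipliers scale activity so herbicide-stressed communities
#' develop less color.
#'
#' @param cfg a [synth_config()].
#' @param design a \code{sample_design}.
#' @return a \code{plate_readings} object: 31 substrates + 1 blank per
#'   sample over the configured time grid.
#' @export
generate_plate_readings <- function(cfg, design) {
  stopifnot(inherits(cfg, "synth_config"))
  pl <- cfg$plate
  subs <- eco_substrates()$substrate
  K <- pl$K[subs]
  assert_that(!any(is.na(K)), "plate K must name all 31 substrates",
              class = "config_error")
  times <- sort(pl$times)
  wells <- c(subs, "Water")
  grid <- expand.grid(time_h = times, substrate = wells,
                      sample_id = design$sample_id, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  m <- pl$activity[design$treatment[match(grid$sample_id, design$sample_id)]]
  m[is.na(m)] <- 1
  Kvec <- c(K, Water = 0)[grid$substrate]
  mean_sig <- Kvec * m / (1 + exp(-pl$r * (grid$time_h - pl$t0)))
  eps <- with_seed(substream_seed(cfg$seed, "plates"),
                   stats::rnorm(nrow(grid), 0, pl$sigma))
  grid$signal <- pmax(mean_sig + eps, 0)
  well_of <- stats::setNames(c(sprintf("w%02d", seq_along(subs)), "w00"), wells)
  grid$well_id <- unname(well_of[grid$substrate])
  plate_readings(grid[, c("sample_id", "well_id", "substrate", "time_h",
                          "signal")])
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper drawing the design, plates, taxa tables and gene
#' table under one configuration.
#'
#' @param cfg a [synth_config()].
#' @return list with \code{design}, \code{plates}, \code{genus},
#'   \code{phylum}, \code{genes}, \code{truth}.
#' @export
generate_synthetic_study <- function(cfg = synth_config()) {
  design <- generate_design(cfg)
  taxa <- generate_taxon_table(cfg, design)
  list(design = design,
       plates = generate_plate_readings(cfg, design),
       genus = taxa$genus,
       phylum = taxa$phylum,
       genes = generate_gene_table(cfg, taxa$genus),
       truth = taxa$truth)
}

#' Write a synthetic study to a directory
#'
#' Emits \code{metadata.csv}, \code{plates.csv}, \code{genus.tsv},
#' \code{phylum.tsv}, \code{genes.tsv} and \code{ground_truth.yaml}.
#'
#' @param study result of [generate_synthetic_study()].
#' @param dir output directory (created if absent).
#' @return invisibly, \code{dir}.
#' @export
write_synthetic_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(unclass(study$design)),
                   file.path(dir, "metadata.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(study$plates)),
                   file.path(dir, "plates.csv"), row.names = FALSE)
  write_abundance_table(study$genus, file.path(dir, "genus.tsv"))
  write_abundance_table(study$phylum, file.path(dir, "phylum.tsv"))
  write_abundance_table(study$genes, file.path(dir, "genes.tsv"))
  truth <- list(
    planted_edges = study$truth$planted_edges,
    responders = study$truth$responders,
    loading_nonzero = which(study$truth$loadings != 0, arr.ind = TRUE)
  )
  writeLines(yaml::as.yaml(truth), file.path(dir, "ground_truth.yaml"))
  invisible(dir)
}
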