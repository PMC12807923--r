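# Small table engineered so pairwise correlations are known: rows are
# monotone copies (rho 1), reversed copies (rho -1) or independent noise.
# A filler row equalizes column totals so the closure to relative
# abundance inside build_network rescales all columns uniformly and
# preserves the engineered rank relations.
engineered_table <- function(n = 30, seed = 2) {
  set.seed(seed)
  base <- rnorm(n)
  m <- rbind(
    up1 = base + 1,
    up2 = exp(base),            # rho(up1, up2) = 1
    down = -base,               # rho -1 vs up*
    noise1 = rnorm(n),
    noise2 = rnorm(n)
  )
  m <- m - min(m) + 0.01        # abundances must be nonnegative
  m <- rbind(m, zfiller = max(colSums(m)) + 1 - colSums(m))
  colnames(m) <- paste0("s", seq_len(n))
  abundance_table(m, rank = "genus")
}

test_that("edges respect both rho and p thresholds and carry signs", {
  tab <- engineered_table()
  net <- build_network(tab, network_spec("taxa", top_k = 6))
  key <- edge_key(net$edges$a, net$edges$b)
  expect_true(edge_key("up1", "up2") %in% key)
  expect_true(edge_key("up1", "down") %in% key)
  sgn <- setNames(net$edges$sign, key)
  expect_equal(unname(sgn[edge_key("up1", "up2")]), "+")
  expect_equal(unname(sgn[edge_key("up1", "down")]), "-")
  # independent noise never reaches |rho| > 0.9 here
  expect_false(any(grepl("noise", key)))
  expect_true(all(net$nodes$degree >= 1))
})

test_that("an edge passing the rho threshold is still dropped by the p threshold", {
  # n = 6, one adjacent swap: rho = 1 - 6*2/210 = 0.943 but p ~ 0.005
  m <- rbind(a = 1:6, b = c(1, 2, 3, 5, 4, 6), c = 2 * (1:6))
  m <- rbind(m, zfiller = max(colSums(m)) + 1 - colSums(m))
  colnames(m) <- paste0("s", 1:6)
  tab <- abundance_table(m, rank = "genus")
  cr <- spearman_matrix(m)
  expect_gt(cr$rho["a", "b"], 0.9)
  expect_gt(cr$p["a", "b"], 0.001)
  net <- build_network(tab, network_spec("taxa", top_k = 4,
                                         p_threshold = 0.001))
  key <- edge_key(net$edges$a, net$edges$b)
  expect_false(edge_key("a", "b") %in% key)   # rho passes, p does not
  expect_true(edge_key("a", "c") %in% key)    # rho = 1, p = 0

  # and a fully sub-threshold table yields an empty network with a warning
  set.seed(30)
  nz <- matrix(rlnorm(4 * 20), 4, 20,
               dimnames = list(paste0("f", 1:4), paste0("s", 1:20)))
  expect_warning(net0 <- build_network(abundance_table(nz, "genus"),
                                       network_spec("taxa", top_k = 4)),
                 "no edge")
  expect_equal(nrow(net0$edges), 0L)
})

test_that("treatment selector restricts the samples entering correlation", {
  cfg <- synth_config(seed = 6, n_genera = 40,
                      blocks = list(list(ranks = 1:5, rho = 0.95)))
  d <- generate_design(cfg)
  tt <- generate_taxon_table(cfg, d)
  spCK <- network_spec("taxa", top_k = 40, treatment = "CK")
  netCK <- suppressWarnings(build_network(tt$genus, spCK, design = d))
  expect_error(build_network(tt$genus, spCK), class = "config_error")
  expect_s3_class(netCK, "co_network")
})

test_that("planted blocks are recovered and non-block genera stay unconnected", {
  cfg <- synth_config(seed = 1, blocks = list(list(ranks = 11:15, rho = 0.98)))
  tt <- generate_taxon_table(cfg, generate_design(cfg))
  net <- build_network(tt$genus, network_spec("taxa"))
  planted <- edge_key(tt$truth$planted_edges$a, tt$truth$planted_edges$b)
  found <- edge_key(net$edges$a, net$edges$b)
  expect_gte(sum(planted %in% found), 8L)
  nonblock <- sprintf("g%03d", 26:45)
  expect_equal(sum(net$edges$a %in% nonblock & net$edges$b %in% nonblock), 0L)
})

test_that("raising rho or lowering p thresholds never adds an edge", {
  tab <- engineered_table(n = 25, seed = 3)
  base <- suppressWarnings(
    build_network(tab, network_spec("taxa", top_k = 6, rho_threshold = 0.5)))
  key0 <- edge_key(base$edges$a, base$edges$b)
  for (thr in c(0.7, 0.9, 0.99)) {
    net <- suppressWarnings(
      build_network(tab, network_spec("taxa", top_k = 6, rho_threshold = thr)))
    expect_true(all(edge_key(net$edges$a, net$edges$b) %in% key0))
    key0_inner <- edge_key(net$edges$a, net$edges$b)
  }
  for (pthr in c(0.05, 0.01, 0.001)) {
    net <- suppressWarnings(
      build_network(tab, network_spec("taxa", top_k = 6, rho_threshold = 0.5,
                                      p_threshold = pthr)))
    expect_true(all(edge_key(net$edges$a, net$edges$b) %in% key0))
  }
})

test_that("taxa-gene network links genes to the phyla they load on", {
  st <- generate_synthetic_study(synth_config(seed = 1))
  net <- build_taxa_gene_network(st$phylum, st$genes)
  expect_true(all(c("phylum", "gene") %in% net$nodes$node_class))
  counts <- attr(net, "gene_phylum_counts")
  expect_true(all(counts >= 1L))

  # noiseless monotone gene-of-one-phylum must produce that edge with "+"
  ph <- st$phylum$matrix
  g <- matrix(2 * ph["p01", ] + 1, 1, ncol(ph),
              dimnames = list("nifH", colnames(ph)))
  gt <- abundance_table(g, rank = "gene")
  expect_warning(net1 <- build_taxa_gene_network(st$phylum, gt),
                 "lacks marker")
  key <- edge_key(net1$edges$a, net1$edges$b)
  expect_true(edge_key("p01", "nifH") %in% key)
  sgn <- setNames(net1$edges$sign, key)
  expect_equal(unname(sgn[edge_key("p01", "nifH")]), "+")
})

test_that("independent genes produce no spurious taxa-gene edges", {
  false_edges <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    n <- 63
    P <- matrix(rlnorm(30 * n), 30, n,
                dimnames = list(sprintf("p%02d", 1:30), paste0("s", 1:n)))
    G <- matrix(rlnorm(12 * n), 12, n,
                dimnames = list(unlist(cn_cycle_genes(), use.names = FALSE),
                                paste0("s", 1:n)))
    net <- suppressWarnings(
      build_taxa_gene_network(abundance_table(P, "phylum"),
                              abundance_table(G, "gene")))
    if (nrow(net$edges)) {
      cls <- setNames(net$nodes$node_class, net$nodes$feature_id)
      false_edges <- false_edges +
        sum(xor(cls[net$edges$a] == "gene", cls[net$edges$b] == "gene"))
    }
  }
  expect_lte(false_edges, 1L)
})

test_that("topology matches hand-enumerated values on small graphs", {
  tri <- co_network(
    data.frame(feature_id = c("a", "b", "c"), stringsAsFactors = FALSE),
    data.frame(a = c("a", "b", "a"), b = c("b", "c", "c"),
               rho = c(0.9, 0.9, -0.9), p = rep(0.01, 3)))
  tp <- topology(tri)
  expect_equal(tp$n_nodes, 3L)
  expect_equal(tp$n_edges, 3L)
  expect_equal(tp$diameter, 1)
  expect_equal(tp$avg_path_length, 1)
  expect_equal(tp$avg_degree, 2)
  expect_equal(tp$pos_ratio_pct, 100 * 2 / 3)
  expect_equal(tp$pos_ratio_pct + tp$neg_ratio_pct, 100, tolerance = 1e-9)

  path4 <- co_network(
    data.frame(feature_id = letters[1:4], stringsAsFactors = FALSE),
    data.frame(a = c("a", "b", "c"), b = c("b", "c", "d"),
               rho = rep(0.95, 3), p = rep(0.01, 3)))
  tp4 <- topology(path4)
  expect_equal(tp4$diameter, 3)
  expect_equal(tp4$avg_path_length, 10 / 6, tolerance = 1e-12)
  expect_equal(tp4$avg_degree, 1.5)
})

test_that("topology of an empty network is all-missing", {
  empty <- co_network(data.frame(feature_id = character()),
                      data.frame(a = character(), b = character(),
                                 rho = numeric(), p = numeric()))
  tp <- topology(empty)
  expect_true(all(is.na(unlist(tp))))
})

test_that("path metrics agree with a Floyd-Warshall oracle on random graphs", {
  set.seed(14)
  for (i in 1:30) {
    n <- sample(5:30, 1)
    m <- sample(n:min(2 * n, n * (n - 1) / 2), 1)
    net <- random_network_fixture(n, m, seed = 1000 + i)
    tp <- topology(net)
    fw <- fw_metrics(net)
    expect_equal(tp$diameter, fw$diameter)
    expect_equal(tp$avg_path_length, fw$avg_path_length, tolerance = 1e-12)
    expect_equal(tp$avg_degree, 2 * m / n, tolerance = 1e-12)
  }
})

test_that("hub detection returns the star center and honors ties", {
  star <- co_network(
    data.frame(feature_id = c("hub", paste0("leaf", 1:9)),
               stringsAsFactors = FALSE),
    data.frame(a = "hub", b = paste0("leaf", 1:9), rho = rep(0.95, 9),
               p = rep(0.001, 9)))
  hubs <- hub_nodes(star, 0.95)
  expect_equal(hubs$feature_id, "hub")

  ring <- random_network_fixture(8, 8, seed = 3)  # 2-regular ring
  expect_equal(nrow(hub_nodes(ring, 0.99)), 8L)
})

test_that("hubs of a planted-block network are block members", {
  cfg <- synth_config(seed = 1, blocks = list(list(ranks = 11:15, rho = 0.98)))
  tt <- generate_taxon_table(cfg, generate_design(cfg))
  net <- build_network(tt$genus, network_spec("taxa"))
  hubs <- hub_nodes(net, 0.9)
  block <- sprintf("g%03d", 11:15)
  expect_true(all(hubs$feature_id %in% block))
})
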