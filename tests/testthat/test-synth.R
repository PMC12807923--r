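test_that("design generation produces the full crossing with stable ids", {
  expect_equal(nrow(generate_design(synth_config())), 63L)

  one <- synth_config(treatments = c(CK = 0), n_replicates = 1, days = 0)
  expect_equal(nrow(generate_design(one)), 1L)

  small <- synth_config(treatments = c(CK = 0, T1 = 180), n_replicates = 2,
                        days = c(0, 1, 5))
  d <- generate_design(small)
  expect_equal(nrow(d), 12L)
  expect_true("T1_d5_r2" %in% d$sample_id)
  expect_equal(anyDuplicated(d$sample_id), 0L)
})

test_that("identical config yields bit-identical outputs", {
  cfg <- synth_config(seed = 11, n_genera = 50,
                      blocks = list(list(ranks = 3:7, rho = 0.9)))
  s1 <- generate_synthetic_study(cfg)
  s2 <- generate_synthetic_study(cfg)
  expect_identical(s1$genus$matrix, s2$genus$matrix)
  expect_identical(s1$genes$matrix, s2$genes$matrix)
  expect_identical(s1$plates$signal, s2$plates$signal)
})

test_that("genus columns are closed and phylum table aggregates genera", {
  cfg <- synth_config(seed = 2, n_genera = 60, blocks = list())
  d <- generate_design(cfg)
  tt <- generate_taxon_table(cfg, d)
  expect_true(all(abs(colSums(tt$genus$matrix) - 1) <= 1e-9))
  expect_true(all(abs(colSums(tt$phylum$matrix) - 1) <= 1e-9))
  # phylum row equals the sum of its member genera
  pmap <- tt$genus$feature_parent
  p1 <- names(which.max(table(pmap)))
  members <- names(pmap)[pmap == p1]
  expect_equal(unname(tt$phylum$matrix[p1, ]),
               unname(colSums(tt$genus$matrix[members, , drop = FALSE])))
})

test_that("zero noise with no blocks or responders gives identical columns", {
  cfg <- synth_config(seed = 3, n_genera = 20, sigma_taxa = 0,
                      blocks = list(), responders = list())
  tt <- generate_taxon_table(cfg, generate_design(cfg))
  m <- tt$genus$matrix
  expect_true(all(abs(m - m[, 1]) < 1e-12))
})

test_that("a planted 5-genus block at rho 0.98 has all pairwise Spearman > 0.8", {
  cfg <- synth_config(seed = 1, blocks = list(list(ranks = 11:15, rho = 0.98)))
  tt <- generate_taxon_table(cfg, generate_design(cfg))
  ids <- sprintf("g%03d", 11:15)
  rho <- cor(t(tt$genus$matrix[ids, ]), method = "spearman")
  expect_true(all(rho[upper.tri(rho)] > 0.8))
})

test_that("responder genus rises only in its treatment after application", {
  cfg <- synth_config(seed = 4,
                      responders = list(list(genus = "g005", treatment = "T5",
                                             days = c(1, 60), fold = 10)))
  d <- generate_design(cfg)
  tt <- generate_taxon_table(cfg, d)
  x <- tt$genus$matrix["g005", ]
  t5_post <- d$sample_id[d$treatment == "T5" & d$day > 0]
  ck <- d$sample_id[d$treatment == "CK"]
  t5_day0 <- d$sample_id[d$treatment == "T5" & d$day == 0]
  expect_gt(mean(x[t5_post]), mean(x[ck]))
  # pre-treatment day-0 samples receive no effect
  expect_lt(mean(x[t5_day0]), mean(x[t5_post]) / 2)
})

test_that("gene table has the 18 fixed ids and tracks its loading genus", {
  cfg <- synth_config(seed = 1, n_genera = 100)
  d <- generate_design(cfg)
  tt <- generate_taxon_table(cfg, d)
  genes <- generate_gene_table(cfg, tt$genus)
  expect_equal(nrow(genes$matrix), 18L)
  expect_setequal(rownames(genes$matrix),
                  c(unlist(cn_cycle_genes(), use.names = FALSE),
                    cazy_families()))

  # noiseless single-loading gene is a monotone image of its genus
  L <- matrix(0, 18, 100,
              dimnames = list(rownames(genes$matrix), sprintf("g%03d", 1:100)))
  L["nifH", "g007"] <- 1
  cfg0 <- synth_config(seed = 1, n_genera = 100, sigma_gene = 0,
                       gene_loadings = L)
  g0 <- generate_gene_table(cfg0, tt$genus)
  expect_equal(unname(cor(g0$matrix["nifH", ], tt$genus$matrix["g007", ],
                          method = "spearman")), 1)
  # all-zero loading row is constant zero
  expect_true(all(g0$matrix["mcrA", ] == 0))
})

test_that("plate kinetics respect the logistic model and null substrates", {
  # sigma 0, K = 100 everywhere, read at t0: signal = 50 * activity
  subs <- eco_substrates()$substrate
  cfg <- synth_config(
    seed = 1, treatments = c(CK = 0, T5 = 900), n_replicates = 1, days = 0,
    plate = list(K = setNames(rep(100, 31), subs), sigma = 0, t0 = 48,
                 times = c(48, 96), activity = c(CK = 1, T5 = 0.75)))
  pr <- generate_plate_readings(cfg, generate_design(cfg))
  at_t0 <- pr[pr$time_h == 48 & pr$substrate != "Water", ]
  expect_equal(unique(at_t0$signal[at_t0$sample_id == "CK_d0_r1"]), 50)
  expect_equal(unique(at_t0$signal[at_t0$sample_id == "T5_d0_r1"]), 37.5)

  # treatment scaling carries into AWCD at 96 h
  prof <- blank_correct(pr, time_h = 96)
  a <- awcd(prof)
  expect_lt(a["T5_d0_r1"], a["CK_d0_r1"])

  # defaults: null substrates have zero blank-corrected activity (noise-free)
  cfg2 <- synth_config(seed = 1, treatments = c(CK = 0), n_replicates = 1,
                       days = 0, plate = list(sigma = 0))
  pr2 <- generate_plate_readings(cfg2, generate_design(cfg2))
  prof2 <- blank_correct(pr2, time_h = 96)
  expect_equal(unname(prof2$activity[1, "2-Hydroxy Benzoic Acid"]), 0)
  expect_equal(unname(prof2$activity[1, "alpha-Ketobutyric Acid"]), 0)
})

test_that("planted blocks separate from background correlation", {
  cfg <- synth_config(seed = 1)
  tt <- generate_taxon_table(cfg, generate_design(cfg))
  rho <- cor(t(tt$genus$matrix[1:60, ]), method = "spearman")
  pe <- tt$truth$planted_edges
  within <- mean(abs(rho[cbind(pe$a, pe$b)]))
  free <- setdiff(rownames(rho), unique(c(pe$a, pe$b)))
  off <- abs(rho[free, free])
  between <- mean(off[upper.tri(off)])
  expect_gt(within - between, 0.5)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(blocks = list(list(ranks = 290:310, rho = 0.9))),
               class = "config_error")
  expect_error(synth_config(blocks = list(list(ranks = 1:5, rho = 1.2))),
               class = "config_error")
  expect_error(synth_config(responders = list(list(genus = "g001",
                                                   treatment = "T1",
                                                   days = c(1, 5),
                                                   fold = -2))),
               class = "config_error")
  expect_error(synth_config(plate = list(times = c(0, 48))),
               class = "config_error")
})

test_that("study writer emits the expected files", {
  cfg <- synth_config(seed = 5, n_genera = 30, days = c(0, 1),
                      n_replicates = 2, blocks = list(),
                      responders = list())
  st <- generate_synthetic_study(cfg)
  dir <- withr::local_tempdir()
  write_synthetic_study(st, dir)
  expect_true(all(file.exists(file.path(dir,
    c("metadata.csv", "plates.csv", "genus.tsv", "phylum.tsv", "genes.tsv",
      "ground_truth.yaml")))))
  back <- read_abundance_table(file.path(dir, "genus.tsv"), "genus")
  expect_equal(back$matrix, st$genus$matrix, tolerance = 1e-6)
})
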