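# Fixtures are built in code at test time; nothing binary ships with the
# package.

# A tiny valid plate CSV: `n_samples` plates, all 31 catalog substrates +
# a Water blank, constant time grid.
write_plate_fixture <- function(path, n_samples = 3, times = c(0, 96),
                                signal = 100, blank = 20) {
  subs <- c(eco_substrates()$substrate, "Water")
  rows <- expand.grid(time_h = times, substrate = subs,
                      sample_id = sprintf("s%02d", seq_len(n_samples)),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  rows$well_id <- match(rows$substrate, subs)
  rows$signal <- ifelse(rows$substrate == "Water", blank, signal)
  write.csv(rows[, c("sample_id", "well_id", "substrate", "time_h", "signal")],
            path, row.names = FALSE)
  path
}

# Small design for comparison tests: k treatments x r replicates x days.
design_fixture <- function(treatments = c("CK", "T1", "T5"), days = c(0, 30),
                           reps = 3) {
  g <- expand.grid(replicate = seq_len(reps), day = days,
                   treatment = treatments, stringsAsFactors = FALSE)
  sample_design(sprintf("%s_d%d_r%d", g$treatment, g$day, g$replicate),
                g$treatment, g$day, g$replicate)
}

# Random co_network on n nodes / m edges where every node has degree >= 1
# (ring backbone + random chords).
random_network_fixture <- function(n, m, seed = 1) {
  stopifnot(m >= n)
  set.seed(seed)
  ids <- sprintf("n%03d", seq_len(n))
  ring <- cbind(seq_len(n), c(2:n, 1L))
  all_pairs <- t(combn(n, 2))
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  pool <- all_pairs[!(key(all_pairs[, 1], all_pairs[, 2]) %in%
                        key(ring[, 1], ring[, 2])), , drop = FALSE]
  extra <- pool[sample(nrow(pool), m - n), , drop = FALSE]
  eidx <- rbind(ring, extra)
  edges <- data.frame(a = ids[eidx[, 1]], b = ids[eidx[, 2]],
                      rho = runif(m, -1, 1), p = runif(m, 0, 0.05),
                      stringsAsFactors = FALSE)
  nodes <- data.frame(feature_id = ids, rank = "genus",
                      phylum = sample(sprintf("p%02d", 1:5), n, replace = TRUE),
                      mean_abundance = runif(n), stringsAsFactors = FALSE)
  co_network(nodes, edges, mode = "taxa")
}

# Independent oracle: Floyd-Warshall all-pairs shortest paths on the
# unit-weight adjacency of a co_network.
fw_metrics <- function(network) {
  ids <- network$nodes$feature_id
  n <- length(ids)
  d <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  for (r in seq_len(nrow(network$edges))) {
    a <- network$edges$a[r]; b <- network$edges$b[r]
    d[a, b] <- d[b, a] <- 1
  }
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], "+"))
  ut <- d[upper.tri(d)]
  finite <- ut[is.finite(ut)]
  # diameter restricted to the largest connected component
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1L
      comp[is.finite(d[i, ])] <- cid
    }
  }
  big <- which(comp == which.max(tabulate(comp)))
  list(diameter = max(d[big, big]), avg_path_length = mean(finite))
}

# Closed-form Spearman on tie-free data: 1 - 6 sum(d^2) / (n (n^2 - 1)).
spearman_d2 <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
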