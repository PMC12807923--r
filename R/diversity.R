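## Alpha/beta diversity and ordination of feature-abundance tables.

#' Close an abundance table to relative abundances
#'
#' Divides each sample column by its total. Already-relative tables are
#' returned unchanged.
#'
#' @param table an \code{abundance_table}.
#' @return the table with \code{is_relative = TRUE} and unit column sums.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$is_relative) return(table)
  cs <- colSums(table$matrix)
  bad <- colnames(table$matrix)[cs == 0]
  if (length(bad))
    stop2("all-zero sample column(s): ", paste(bad, collapse = ", "))
  abundance_table(sweep(table$matrix, 2L, cs, "/"), rank = table$rank,
                  is_relative = TRUE, feature_parent = table$feature_parent)
}

#' Select the k most abundant features
#'
#' Ranks features by mean relative abundance across the given samples
#' (the table is closed first if it is not already relative); ties at the
#' cut are broken lexicographically by feature id. Used to pick the top
#' 300 genera / top 30 phyla entering network construction.
#'
#' @param table an \code{abundance_table}.
#' @param k number of features to keep.
#' @param samples optional character vector restricting the samples over
#'   which means are taken (selection only; all columns are returned).
#' @return an \code{abundance_table} with at most \code{k} features,
#'   ordered by decreasing mean relative abundance.
#' @export
top_k_features <- function(table, k, samples = NULL) {
  stopifnot(inherits(table, "abundance_table"), k >= 1)
  rel <- relative_abundance(table)
  m <- rel$matrix
  sel <- if (is.null(samples)) m else m[, samples, drop = FALSE]
  mu <- rowMeans(sel)
  ord <- order(-mu, rownames(m))
  if (k > nrow(m)) {
    warn2("k = ", k, " exceeds feature count ", nrow(m), "; returning all")
    k <- nrow(m)
  }
  keep <- ord[seq_len(k)]
  ## a feature subset is no longer closed, so it is never declared relative
  abundance_table(table$matrix[keep, , drop = FALSE], rank = table$rank,
                  is_relative = FALSE,
                  feature_parent = table$feature_parent)
}

#' Shannon diversity index
#'
#' \eqn{H = -\sum p_i \ln p_i} with natural logarithm, computed through
#' \code{vegan::diversity}. Accepts counts or relative abundances.
#'
#' @param counts nonnegative numeric vector with positive sum.
#' @return Shannon index (scalar).
#' @export
shannon_index <- function(counts) {
  assert_that(length(counts) > 0 && sum(counts) > 0,
              "shannon_index needs a nonempty vector with positive sum")
  assert_that(all(counts >= 0), "negative abundances")
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Chao1 richness estimator
#'
#' Bias-corrected form \eqn{S_{obs} + F_1 (F_1 - 1) / (2 (F_2 + 1))} by
#' default (defined even without doubletons); the classical
#' \eqn{S_{obs} + F_1^2 / (2 F_2)} is available via
#' \code{form = "classic"}. \eqn{F_1}/\eqn{F_2} are singleton/doubleton
#' counts, which only exist for raw integer counts — relative abundances
#' are rejected.
#'
#' @param counts nonnegative integer counts.
#' @param form \code{"bias_corrected"} (default) or \code{"classic"}.
#' @return Chao1 estimate (scalar, >= observed richness).
#' @export
chao1 <- function(counts, form = c("bias_corrected", "classic")) {
  form <- match.arg(form)
  assert_that(all(counts >= 0), "negative counts")
  if (any(abs(counts - round(counts)) > 1e-9))
    stop2("chao1 requires raw integer counts; richness estimation is ",
          "undefined on relative abundances")
  counts <- round(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (form == "bias_corrected") s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  else if (f1 == 0) s_obs
  else s_obs + f1^2 / (2 * max(f2, 1))
}

#' Alpha diversity per sample
#'
#' Shannon (and, for integer tables, Chao1) for every sample column.
#' Shannon is computed on counts when available, otherwise on relative
#' abundances (noted in the output attribute \code{"input"}).
#'
#' @param table an \code{abundance_table}.
#' @return data frame with \code{sample_id}, \code{shannon}, \code{chao1}
#'   (Chao1 is \code{NA} for non-integer tables).
#' @export
alpha_diversity <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  m <- table$matrix
  is_int <- all(abs(m - round(m)) <= 1e-9)
  out <- data.frame(
    sample_id = colnames(m),
    shannon = apply(m, 2L, shannon_index),
    chao1 = if (is_int) apply(m, 2L, chao1) else NA_real_,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "input") <- if (is_int) "counts" else "relative"
  out
}

#' Bray-Curtis dissimilarity
#'
#' \eqn{BC(x,y) = \sum |x_i - y_i| / \sum (x_i + y_i)} between sample
#' columns, via \code{vegan::vegdist}. Note Bray-Curtis is not invariant
#' to a joint rescaling of one sample's total; close tables with
#' [relative_abundance()] first when totals are arbitrary.
#'
#' @param table an \code{abundance_table}.
#' @return symmetric samples x samples matrix with zero diagonal.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  m <- t(table$matrix)
  zero <- rowSums(m) == 0
  if (sum(zero) >= 2L)
    stop2("Bray-Curtis undefined between all-zero samples: ",
          paste(rownames(m)[zero], collapse = ", "))
  as.matrix(vegan::vegdist(m, method = "bray"))
}

.ordination <- function(scores, eig, method) {
  pos <- eig[eig > 0]
  pct <- if (length(pos) == 0L) rep(0, ncol(scores))
         else 100 * pos[seq_len(min(ncol(scores), length(pos)))] / sum(pos)
  structure(list(scores = scores, eigenvalues = eig,
                 percent_explained = pct, method = method),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat("<ordination_result ", x$method, "> ", nrow(x$scores), " samples, ",
      ncol(x$scores), " axes (",
      paste(sprintf("%.1f%%", x$percent_explained), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a dissimilarity matrix (double-centering of
#' \eqn{-D^2/2} and eigendecomposition, via \code{stats::cmdscale}).
#' Negative eigenvalues (non-Euclidean input) are dropped and their total
#' magnitude reported in the \code{"lost_inertia"} attribute; percent
#' explained is relative to positive inertia. On Euclidean distances PCoA
#' scores match PCA scores up to axis sign.
#'
#' @param dissimilarity symmetric dissimilarity matrix.
#' @param n_axes number of axes requested.
#' @return an \code{ordination_result}; fewer axes than requested are
#'   returned (with a warning) when positive eigenvalues run out.
#' @export
pcoa <- function(dissimilarity, n_axes = 2) {
  d <- as.matrix(dissimilarity)
  assert_that(isTRUE(all.equal(d, t(d), tolerance = 1e-8)),
              "dissimilarity matrix must be symmetric")
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = min(n_axes, nrow(d) - 1L),
                    eig = TRUE))
  eig <- fit$eig
  n_pos <- sum(eig > 1e-12)
  if (n_pos == 0L) {
    ## degenerate: all points identical
    scores <- matrix(0, nrow(d), n_axes,
                     dimnames = list(rownames(d),
                                     paste0("Axis", seq_len(n_axes))))
    return(.ordination(scores, eig = rep(0, n_axes), method = "pcoa"))
  }
  if (n_axes > n_pos) {
    warn2("only ", n_pos, " positive eigenvalues; returning ", n_pos, " axes")
    n_axes <- n_pos
  }
  scores <- fit$points[, seq_len(n_axes), drop = FALSE]
  colnames(scores) <- paste0("Axis", seq_len(n_axes))
  res <- .ordination(scores, eig = eig[eig > 1e-12], method = "pcoa")
  attr(res, "lost_inertia") <- sum(abs(eig[eig < 0]))
  res
}

#' PCA on Euclidean distances
#'
#' Principal component analysis of sample columns (features as variables,
#' centered, unscaled; \code{stats::prcomp}). Equivalent to PCoA of the
#' Euclidean distance matrix.
#'
#' @param table an \code{abundance_table}.
#' @param n_axes number of components.
#' @return an \code{ordination_result}.
#' @export
pca_euclidean <- function(table, n_axes = 2) {
  stopifnot(inherits(table, "abundance_table"))
  x <- t(table$matrix)
  assert_that(nrow(x) >= 2L, "PCA needs at least 2 samples")
  if (all(apply(x, 2L, stats::var) < 1e-300))
    stop2("constant table: zero variance in every feature")
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  eig <- fit$sdev^2
  n_axes <- min(n_axes, sum(eig > 1e-12))
  scores <- fit$x[, seq_len(n_axes), drop = FALSE]
  colnames(scores) <- paste0("Axis", seq_len(n_axes))
  .ordination(scores, eig = eig[eig > 1e-12], method = "pca_euclidean")
}
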