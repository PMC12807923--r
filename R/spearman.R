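## Spearman correlation matrices with significance, the primitive behind
## network construction. Rho is the Pearson correlation of midranks
## (stats::cor, method = "spearman"); p-values come from the two-sided t
## approximation t = rho * sqrt((n-2)/(1-rho^2)) on n-2 df, vectorized
## over the whole matrix, with a seeded permutation alternative for small
## n.

#' Spearman correlation matrix with p-values
#'
#' Computes all pairwise Spearman correlations between the rows of a
#' features x samples matrix, with two-sided significance. Zero-variance
#' features (constant across samples) get \eqn{\rho = 0}, \eqn{p = 1}
#' against everything, so they can never enter a thresholded network.
#'
#' @param X numeric matrix, features in rows, samples in columns (>= 4
#'   samples), or an \code{abundance_table}.
#' @param p_method \code{"t_approx"} (default) or \code{"permutation"}
#'   (exact null resampling, recommended below ~10 samples).
#' @param n_perm permutations when \code{p_method = "permutation"}.
#' @param perm_seed seed for the permutation draw.
#' @return list of class \code{correlation_result}: \code{rho} and
#'   \code{p} (symmetric matrices, unit/zero diagonal), \code{n_obs}.
#' @export
spearman_matrix <- function(X, p_method = c("t_approx", "permutation"),
                            n_perm = 10000L, perm_seed = 1L) {
  p_method <- match.arg(p_method)
  if (inherits(X, "abundance_table")) X <- X$matrix
  n <- ncol(X)
  assert_that(n >= 4L, "need at least 4 samples for Spearman p-values")
  const <- apply(X, 1L, function(r) length(unique(r)) == 1L)
  rho <- suppressWarnings(stats::cor(t(X), method = "spearman"))
  rho[const, ] <- 0
  rho[, const] <- 0
  diag(rho) <- 1

  if (p_method == "t_approx") {
    r2 <- pmin(rho^2, 1)
    tt <- abs(rho) * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
    p <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
    p[r2 >= 1 - 1e-15] <- 0
  } else {
    p <- .spearman_perm_p(X, rho, n_perm = n_perm, seed = perm_seed)
  }
  p[const, ] <- 1
  p[, const] <- 1
  diag(p) <- 0
  p <- pmin(pmax(p, 0), 1)
  structure(list(rho = rho, p = p, n_obs = n), class = "correlation_result")
}

## Permutation null: permute sample order of each row independently per
## permutation; p = (1 + #{|rho*| >= |rho|}) / (1 + n_perm), shared null
## across pairs of the same n (the Spearman null depends only on n).
.spearman_perm_p <- function(X, rho, n_perm, seed) {
  n <- ncol(X)
  null_abs <- with_seed(seed, {
    rx <- seq_len(n)  # ranks of a fixed tie-free reference
    vapply(seq_len(n_perm), function(i) {
      abs(stats::cor(rx, sample(rx), method = "spearman"))
    }, numeric(1))
  })
  null_sorted <- sort(null_abs)
  m <- nrow(rho)
  p <- matrix(0, m, m, dimnames = dimnames(rho))
  a <- abs(rho)
  ## exceedance count via binary search on the sorted null
  cnt <- n_perm - findInterval(a - 1e-12, null_sorted)
  p[] <- (1 + cnt) / (1 + n_perm)
  p
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("<correlation_result> ", nrow(x$rho), " features, n_obs = ",
      x$n_obs, "\n", sep = "")
  invisible(x)
}
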