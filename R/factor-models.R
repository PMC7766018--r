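# Sparse PCA and sparse CCA built on the rank-one PMD engine with deflation.
# Both operate on column-standardized views, so scores are unit-free and the
# first sparse CCA factor value is (up to scaling) a correlation.

MEMBERSHIP_EPS <- 1e-10

membership_from_loadings <- function(L) {
  lapply(seq_len(ncol(L)), function(k) rownames(L)[abs(L[, k]) > MEMBERSHIP_EPS])
}

overlap_counts <- function(membership) {
  K <- length(membership)
  out <- matrix(0L, K, K,
                dimnames = list(paste0("comp", seq_len(K)),
                                paste0("comp", seq_len(K))))
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      out[i, j] <- length(intersect(membership[[i]], membership[[j]]))
    }
  }
  out
}

comp_names <- function(K) paste0("comp", seq_len(K))

#' Sparse principal components analysis
#'
#' Extracts sparse principal components of one view by penalized matrix
#' decomposition applied to the column-standardized data matrix: the sample
#' side of each rank-one factor is unpenalized while the loading side carries
#' the L1 budget, and successive components are obtained after deflating the
#' fitted rank-one term. Features with non-zero loadings "participate" in a
#' component; membership lists and pairwise component overlaps are reported
#' alongside the scores used for phenotype-separation plots.
#'
#' @param data View tibble (sample column, optional label column, numeric
#'   features).
#' @param penalty L1 budget on the loadings, between 1 and `sqrt(p)`;
#'   `sqrt(p)` (the default) is inactive and reproduces dense PCA.
#' @param n_components Number of components (must not exceed the rank of the
#'   standardized matrix).
#' @param standardize Standardize columns first (default `TRUE`; set `FALSE`
#'   only if `data` is already standardized).
#' @param tol,max_iter Convergence controls passed to [pmd_rank1()].
#' @param sample_col,label_col Identifier column names.
#' @return Object of class `sparse_pca`: loadings (p x K), scores (n x K,
#'   computed as standardized data times loadings), factor values `d`,
#'   per-component membership, overlap counts, convergence info, labels.
#' @seealso [tidy.sparse_pca()], [autoplot.sparse_pca()], [sparse_cca()]
#' @export
sparse_pca <- function(data, penalty = NULL, n_components = 2L,
                       standardize = TRUE, tol = 1e-8, max_iter = 1000L,
                       sample_col = "sample", label_col = "label") {
  parts <- view_parts(data, sample_col, label_col)
  Xs <- if (standardize) standardize_matrix(parts$values) else parts$values
  n <- nrow(Xs); p <- ncol(Xs)
  if (is.null(penalty)) penalty <- sqrt(p)
  if (n_components < 1L) stop("`n_components` must be >= 1", call. = FALSE)
  rk <- qr(Xs)$rank
  if (n_components > rk) {
    stop("`n_components` (", n_components, ") exceeds the matrix rank (", rk,
         ")", call. = FALSE)
  }
  R <- Xs
  loadings <- matrix(0, p, n_components,
                     dimnames = list(parts$feature_ids,
                                     comp_names(n_components)))
  d <- numeric(n_components)
  iterations <- integer(n_components)
  converged <- logical(n_components)
  for (k in seq_len(n_components)) {
    fac <- pmd_rank1(R, c1 = sqrt(n), c2 = penalty, tol = tol,
                     max_iter = max_iter)
    # sign convention on the loading side: largest-magnitude loading positive
    i_max <- which.max(abs(fac$v))
    s <- if (fac$v[i_max] < 0) -1 else 1
    loadings[, k] <- s * fac$v
    d[k] <- fac$d
    iterations[k] <- fac$iterations
    converged[k] <- fac$converged
    R <- R - fac$d * tcrossprod(fac$u, fac$v)
  }
  scores <- Xs %*% loadings
  colnames(scores) <- comp_names(n_components)
  membership <- membership_from_loadings(loadings)
  structure(
    list(loadings = loadings, scores = scores, d = d,
         membership = membership, overlap = overlap_counts(membership),
         penalty = penalty, n_components = n_components,
         sample_ids = parts$sample_ids, labels = parts$labels,
         iterations = iterations, converged = converged),
    class = "sparse_pca")
}

#' @export
print.sparse_pca <- function(x, ...) {
  cat(sprintf("Sparse PCA: %d components, penalty %.4g, %d features, %d samples\n",
              x$n_components, x$penalty, nrow(x$loadings), nrow(x$scores)))
  sizes <- vapply(x$membership, length, integer(1))
  cat("  non-zero loadings per component:", paste(sizes, collapse = ", "), "\n")
  if (x$n_components >= 2L) {
    cat("  features shared by components 1 and 2:", x$overlap[1L, 2L], "\n")
  }
  if (!all(x$converged)) cat("  warning: some components did not converge\n")
  invisible(x)
}

#' Sparse canonical correlation analysis
#'
#' Finds sparse, mutually maximally correlated linear combinations of two
#' views measured on the same samples. With the within-view covariances
#' treated as identity on standardized data (the diagonal treatment required
#' when features vastly outnumber samples), the problem reduces to rank-one
#' penalized decomposition of the cross-product matrix
#' `K = X' Z / (n - 1)`; subsequent components deflate `K` by the fitted
#' rank-one term. Each component reports the sample canonical correlation of
#' its score pair and, per view, the features with non-zero loadings.
#'
#' @param x,z View tibbles sharing the same samples (matched by sample ID;
#'   a mismatch is an error).
#' @param c1,c2 L1 budgets for the x- and z-side loadings (defaults
#'   `sqrt(p)`, `sqrt(q)`: inactive).
#' @param n_components Number of components (default 2, the first and second
#'   canonical components used throughout the analyses).
#' @param standardize Standardize both views first (default `TRUE`).
#' @inheritParams sparse_pca
#' @return Object of class `sparse_cca`: loading matrices `u` (p x K) and `v`
#'   (q x K), factor values `d`, per-component `canonical_correlation`,
#'   score matrices `scores_x`, `scores_z`, per-view membership lists and
#'   overlap counts, convergence info, labels.
#' @seealso [tidy.sparse_cca()], [autoplot.sparse_cca()],
#'   [cca_permutation_test()], [select_penalties()]
#' @export
sparse_cca <- function(x, z, c1 = NULL, c2 = NULL, n_components = 2L,
                       standardize = TRUE, tol = 1e-8, max_iter = 1000L,
                       sample_col = "sample", label_col = "label") {
  px <- view_parts(x, sample_col, label_col)
  pz <- view_parts(z, sample_col, label_col)
  if (!setequal(px$sample_ids, pz$sample_ids)) {
    stop("the two views do not share the same samples", call. = FALSE)
  }
  ord <- match(px$sample_ids, pz$sample_ids)
  Zv <- pz$values[ord, , drop = FALSE]
  Xs <- if (standardize) standardize_matrix(px$values) else px$values
  Zs <- if (standardize) standardize_matrix(Zv) else Zv
  n <- nrow(Xs); p <- ncol(Xs); q <- ncol(Zs)
  if (is.null(c1)) c1 <- sqrt(p)
  if (is.null(c2)) c2 <- sqrt(q)
  if (n_components < 1L) stop("`n_components` must be >= 1", call. = FALSE)

  K <- crossprod(Xs, Zs) / (n - 1)
  u <- matrix(0, p, n_components,
              dimnames = list(px$feature_ids, comp_names(n_components)))
  v <- matrix(0, q, n_components,
              dimnames = list(pz$feature_ids, comp_names(n_components)))
  d <- cancor_k <- numeric(n_components)
  iterations <- integer(n_components)
  converged <- logical(n_components)
  for (k in seq_len(n_components)) {
    fac <- pmd_rank1(K, c1 = c1, c2 = c2, tol = tol, max_iter = max_iter)
    u[, k] <- fac$u
    v[, k] <- fac$v
    d[k] <- fac$d
    iterations[k] <- fac$iterations
    converged[k] <- fac$converged
    sx <- drop(Xs %*% fac$u)
    sz <- drop(Zs %*% fac$v)
    cancor_k[k] <- if (sd(sx) < 1e-12 || sd(sz) < 1e-12) NA_real_ else cor(sx, sz)
    K <- K - fac$d * tcrossprod(fac$u, fac$v)
  }
  scores_x <- Xs %*% u
  scores_z <- Zs %*% v
  mem_x <- membership_from_loadings(u)
  mem_z <- membership_from_loadings(v)
  structure(
    list(u = u, v = v, d = d, canonical_correlation = cancor_k,
         scores_x = scores_x, scores_z = scores_z,
         membership_x = mem_x, membership_z = mem_z,
         overlap_x = overlap_counts(mem_x), overlap_z = overlap_counts(mem_z),
         c1 = c1, c2 = c2, n_components = n_components,
         sample_ids = px$sample_ids, labels = px$labels,
         iterations = iterations, converged = converged),
    class = "sparse_cca")
}

#' @export
print.sparse_cca <- function(x, ...) {
  cat(sprintf("Sparse CCA: %d components, budgets (%.4g, %.4g)\n",
              x$n_components, x$c1, x$c2))
  for (k in seq_len(x$n_components)) {
    cat(sprintf(
      "  comp%d: canonical correlation %.3f, membership %d (x) / %d (z)\n",
      k, x$canonical_correlation[k], length(x$membership_x[[k]]),
      length(x$membership_z[[k]])))
  }
  if (!all(x$converged)) cat("  warning: some components did not converge\n")
  invisible(x)
}
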