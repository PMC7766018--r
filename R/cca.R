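# Classical canonical correlation analysis (whitening + SVD) and the
# exhaustive sub-dimensional subset search it enables on small problems.
# Classical CCA requires more samples than total features; on the study's
# data (12 samples, hundreds of genes) it is infeasible, which is exactly why
# the sparse decomposition exists -- the infeasibility is reported as an
# explicit error rather than a numerical collapse.

# Inverse symmetric square root, guarding against singular covariance.
inv_sqrt_sym <- function(S, what) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < 1e-10 * max(e$values)) {
    stop("within-view covariance of ", what,
         " is singular; classical CCA is infeasible", call. = FALSE)
  }
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Classical canonical correlation analysis
#'
#' Full-rank CCA of two low-dimensional views via whitening and SVD:
#' correlations are the singular values of
#' `Sxx^{-1/2} Sxz Szz^{-1/2}`, and the weight vectors are normalized so the
#' canonical variates have unit variance. Requires `n > p + q` and
#' nonsingular within-view covariances; otherwise an explicit infeasibility
#' error is raised.
#'
#' @inheritParams sparse_cca
#' @return Object of class `classical_cca`: `correlations` (non-increasing,
#'   in \[0, 1\]), weight matrices `xcoef`, `zcoef`, canonical variate score
#'   matrices `scores_x`, `scores_z`, and labels.
#' @export
classical_cca <- function(x, z, sample_col = "sample", label_col = "label") {
  px <- view_parts(x, sample_col, label_col)
  pz <- view_parts(z, sample_col, label_col)
  if (!setequal(px$sample_ids, pz$sample_ids)) {
    stop("the two views do not share the same samples", call. = FALSE)
  }
  Z <- pz$values[match(px$sample_ids, pz$sample_ids), , drop = FALSE]
  X <- px$values
  n <- nrow(X); p <- ncol(X); q <- ncol(Z)
  if (n <= p + q) {
    stop("classical CCA infeasible: need n > p + q but n = ", n,
         ", p + q = ", p + q,
         "; use sparse_cca() or subdimensional_cca()", call. = FALSE)
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  Sxx <- crossprod(Xc) / (n - 1)
  Szz <- crossprod(Zc) / (n - 1)
  Sxz <- crossprod(Xc, Zc) / (n - 1)
  Wx <- inv_sqrt_sym(Sxx, "x")
  Wz <- inv_sqrt_sym(Szz, "z")
  sv <- svd(Wx %*% Sxz %*% Wz)
  r <- min(p, q)
  correlations <- pmin(pmax(sv$d[seq_len(r)], 0), 1)
  xcoef <- Wx %*% sv$u[, seq_len(r), drop = FALSE]
  zcoef <- Wz %*% sv$v[, seq_len(r), drop = FALSE]
  dimnames(xcoef) <- list(px$feature_ids, comp_names(r))
  dimnames(zcoef) <- list(pz$feature_ids, comp_names(r))
  scores_x <- Xc %*% xcoef
  scores_z <- Zc %*% zcoef
  structure(
    list(correlations = correlations, xcoef = xcoef, zcoef = zcoef,
         scores_x = scores_x, scores_z = scores_z,
         sample_ids = px$sample_ids, labels = px$labels,
         n = n, p = p, q = q),
    class = "classical_cca")
}

#' @export
print.classical_cca <- function(x, ...) {
  cat(sprintf("Classical CCA: n = %d, p = %d, q = %d\n", x$n, x$p, x$q))
  cat("  canonical correlations:",
      paste(sprintf("%.3f", x$correlations), collapse = ", "), "\n")
  invisible(x)
}

# First canonical correlation between columns S (subset of x) and the fixed
# whitened z-block; A is the x-side correlation submatrix.
first_cancor_subset <- function(Rxx_sub, B_sub) {
  U <- tryCatch(chol(Rxx_sub), error = function(e) NULL)
  if (is.null(U)) return(NA_real_)
  M <- forwardsolve(t(U), B_sub)
  min(svd(M, nu = 0L, nv = 0L)$d[1L], 1)
}

#' Exhaustive sub-dimensional CCA subset search
#'
#' Evaluates the first classical canonical correlation between every size-`k`
#' subset of the features of `x` and the full view `z`, and ranks subsets by
#' decreasing correlation (ties broken by lexicographic subset order). This is
#' the exhaustive-search predecessor of sparse CCA; it is only tractable for
#' small `k` (3-4) and requires `n > k + q`.
#'
#' @inheritParams sparse_cca
#' @param k Subset size; a warning is issued above 4, where the search space
#'   explodes combinatorially.
#' @param top_m Number of top-ranked subsets to return.
#' @return Object of class `subcca`: tibble `subsets` with columns `rank`,
#'   `features` (';'-joined), `feature_set` (list of character vectors) and
#'   `correlation`, plus `k` and `total_evaluated = choose(p, k)`.
#' @export
subdimensional_cca <- function(x, z, k = 3L, top_m = 10L,
                               sample_col = "sample", label_col = "label") {
  px <- view_parts(x, sample_col, label_col)
  pz <- view_parts(z, sample_col, label_col)
  if (!setequal(px$sample_ids, pz$sample_ids)) {
    stop("the two views do not share the same samples", call. = FALSE)
  }
  Z <- pz$values[match(px$sample_ids, pz$sample_ids), , drop = FALSE]
  n <- nrow(px$values); p <- ncol(px$values); q <- ncol(Z)
  k <- as.integer(k)
  if (k < 1L || k > p) stop("`k` must lie in [1, p]", call. = FALSE)
  if (k > 4L) {
    warning("subset size k = ", k,
            " is above the recommended maximum of 4; the exhaustive search ",
            "may be very slow", call. = FALSE)
  }
  if (n <= k + q) {
    stop("classical CCA infeasible for the subsets: need n > k + q but n = ",
         n, ", k + q = ", k + q, call. = FALSE)
  }
  Xs <- standardize_matrix(px$values)
  Zs <- standardize_matrix(Z)
  Rxx <- crossprod(Xs) / (n - 1)
  Rzz <- crossprod(Zs) / (n - 1)
  Rxz <- crossprod(Xs, Zs) / (n - 1)
  B <- Rxz %*% inv_sqrt_sym(Rzz, "z")

  subsets <- combn(p, k)            # lexicographic order
  m <- ncol(subsets)
  rho <- numeric(m)
  for (j in seq_len(m)) {
    S <- subsets[, j]
    rho[j] <- first_cancor_subset(Rxx[S, S, drop = FALSE],
                                  B[S, , drop = FALSE])
  }
  ord <- order(-rho, seq_len(m))    # ties: lexicographic subset order
  top_m <- min(as.integer(top_m), m)
  top <- ord[seq_len(top_m)]
  feature_sets <- lapply(top, function(j) px$feature_ids[subsets[, j]])
  structure(
    list(subsets = tibble::tibble(
           rank = seq_len(top_m),
           features = vapply(feature_sets, paste, character(1),
                             collapse = ";"),
           feature_set = feature_sets,
           correlation = rho[top]),
         k = k, total_evaluated = m, p = p, q = q, n = n),
    class = "subcca")
}

#' @export
print.subcca <- function(x, ...) {
  cat(sprintf(
    "Sub-dimensional CCA: %d subsets of size %d evaluated (n = %d, q = %d)\n",
    x$total_evaluated, x$k, x$n, x$q))
  print(dplyr::select(x$subsets, "rank", "features", "correlation"))
  invisible(x)
}
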