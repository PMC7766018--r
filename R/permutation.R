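# Permutation machinery for sparse CCA: a calibrated test of the first
# canonical correlation against the sample-permutation null, and a
# permutation-gap rule for choosing the L1 budgets (the field's standard
# answer when no budgets are prescribed).

# First sparse canonical correlation from pre-standardized matrices. Internal
# fast path shared by the permutation routines.
scca_first_cor <- function(Xs, Zs, c1, c2, tol = 1e-7, max_iter = 200L) {
  n <- nrow(Xs)
  K <- crossprod(Xs, Zs) / (n - 1)
  if (all(K == 0)) return(0)
  fac <- pmd_rank1(K, c1 = c1, c2 = c2, tol = tol, max_iter = max_iter)
  sx <- drop(Xs %*% fac$u)
  sz <- drop(Zs %*% fac$v)
  if (sd(sx) < 1e-12 || sd(sz) < 1e-12) return(0)
  cor(sx, sz)
}

#' Permutation test of the first sparse canonical correlation
#'
#' Compares the observed first canonical correlation with its distribution
#' under random row permutations of `z`, which break any cross-view link
#' while preserving both within-view structures. The p-value is the exact
#' Monte-Carlo estimate `(1 + #{perm >= observed}) / (n_perm + 1)`.
#'
#' @inheritParams sparse_cca
#' @param n_perm Number of permutations (default 199).
#' @param seed Seed controlling the permutations.
#' @return List with `observed`, `perm` (vector of permuted correlations),
#'   `p_value`, and the budgets used.
#' @export
cca_permutation_test <- function(x, z, c1 = NULL, c2 = NULL, n_perm = 199L,
                                 seed = 1L, sample_col = "sample",
                                 label_col = "label") {
  px <- view_parts(x, sample_col, label_col)
  pz <- view_parts(z, sample_col, label_col)
  if (!setequal(px$sample_ids, pz$sample_ids)) {
    stop("the two views do not share the same samples", call. = FALSE)
  }
  Z <- pz$values[match(px$sample_ids, pz$sample_ids), , drop = FALSE]
  Xs <- standardize_matrix(px$values)
  Zs <- standardize_matrix(Z)
  n <- nrow(Xs)
  if (is.null(c1)) c1 <- sqrt(ncol(Xs))
  if (is.null(c2)) c2 <- sqrt(ncol(Zs))
  if (n_perm < 1L) stop("`n_perm` must be positive", call. = FALSE)

  observed <- scca_first_cor(Xs, Zs, c1, c2)
  perms <- withr::with_seed(seed, {
    replicate(n_perm, sample.int(n), simplify = FALSE)
  })
  perm <- vapply(perms, function(pm) {
    scca_first_cor(Xs, Zs[pm, , drop = FALSE], c1, c2)
  }, numeric(1))
  p_value <- (1 + sum(perm >= observed)) / (n_perm + 1)
  list(observed = observed, perm = perm, p_value = p_value,
       c1 = c1, c2 = c2, n_perm = as.integer(n_perm))
}

#' Choose sparse CCA budgets by the permutation gap
#'
#' For every candidate budget pair, computes the observed first canonical
#' correlation and its mean over row-permuted replicates of `z` (the same
#' permutations are reused across the grid, for a paired comparison), and
#' selects the pair maximizing the observed-minus-null gap.
#'
#' @inheritParams cca_permutation_test
#' @param c1_grid,c2_grid Numeric vectors of candidate budgets; the grid is
#'   their cross product.
#' @param n_perm Number of permutations per grid point (>= 10).
#' @return List with the selected `c1`, `c2`, and `grid`, a tibble of
#'   (c1, c2, observed, perm_mean, gap) for every candidate.
#' @export
select_penalties <- function(x, z, c1_grid, c2_grid, n_perm = 25L, seed = 1L,
                             sample_col = "sample", label_col = "label") {
  if (length(c1_grid) == 0L || length(c2_grid) == 0L) {
    stop("budget grids must be non-empty", call. = FALSE)
  }
  if (n_perm < 10L) stop("`n_perm` must be at least 10", call. = FALSE)
  px <- view_parts(x, sample_col, label_col)
  pz <- view_parts(z, sample_col, label_col)
  if (!setequal(px$sample_ids, pz$sample_ids)) {
    stop("the two views do not share the same samples", call. = FALSE)
  }
  Z <- pz$values[match(px$sample_ids, pz$sample_ids), , drop = FALSE]
  Xs <- standardize_matrix(px$values)
  Zs <- standardize_matrix(Z)
  n <- nrow(Xs)
  perms <- withr::with_seed(seed, {
    replicate(n_perm, sample.int(n), simplify = FALSE)
  })
  grid <- tidyr::crossing(c1 = sort(unique(c1_grid)),
                          c2 = sort(unique(c2_grid)))
  res <- purrr::pmap_dfr(grid, function(c1, c2) {
    obs <- scca_first_cor(Xs, Zs, c1, c2)
    pm <- vapply(perms, function(idx) {
      scca_first_cor(Xs, Zs[idx, , drop = FALSE], c1, c2)
    }, numeric(1))
    tibble::tibble(c1 = c1, c2 = c2, observed = obs,
                   perm_mean = mean(pm), gap = obs - mean(pm))
  })
  best <- res[which.max(res$gap), ]
  list(c1 = best$c1[[1]], c2 = best$c2[[1]], grid = res)
}
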