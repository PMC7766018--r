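test_that("sparse PCA tracks the high-variance axis and dense PCA", {
  # exactly uncorrelated columns with sample variances 16/3 and 4/3
  M <- cbind(a = 2 * c(1, -1, 1, -1), b = c(1, 1, -1, -1))
  fit <- sparse_pca(as_view(M), n_components = 1L, standardize = FALSE)
  expect_lt(diff_up_to_sign(fit$loadings[, 1], c(1, 0)), 1e-9)

  v <- random_view(12, 8, seed = 23)
  fit2 <- sparse_pca(v, n_components = 2L)
  pr <- stats::prcomp(scale(view_values(v)))
  for (k in 1:2) {
    expect_lt(diff_up_to_sign(fit2$loadings[, k], pr$rotation[, k]), 1e-8)
    expect_lt(diff_up_to_sign(fit2$scores[, k], pr$x[, k]), 1e-7)
  }
})

test_that("sparse PCA membership recovers a noiseless planted support", {
  pv <- simulate_views(sim_scenario(n_per_group = 4, p = 10, q = 4,
                                    support_x = 4, support_z = 2,
                                    noise_sd_x = 0, noise_sd_z = 0,
                                    effect = 2, seed = 6))
  fit <- sparse_pca(pv$x, penalty = 2, n_components = 1L)
  expect_setequal(fit$membership[[1]],
                  names(pv$truth$true_u)[pv$truth$support_x])
})

test_that("sparse PCA validates the component count against the rank", {
  v <- random_view(4, 8, seed = 29)   # rank 3 after centering
  expect_error(sparse_pca(v, n_components = 4L), "rank")
})

test_that("sparse CCA recovers a shared noiseless factor exactly", {
  pv <- simulate_views(sim_scenario(n_per_group = 4, p = 9, q = 7,
                                    support_x = 3, support_z = 2,
                                    noise_sd_x = 0, noise_sd_z = 0,
                                    effect = 2, seed = 15))
  fit <- sparse_cca(pv$x, pv$z, c1 = sqrt(3), c2 = sqrt(2),
                    n_components = 1L)
  expect_equal(fit$canonical_correlation[1], 1, tolerance = 1e-8)
  expect_setequal(fit$membership_x[[1]],
                  names(pv$truth$true_u)[pv$truth$support_x])
  expect_setequal(fit$membership_z[[1]],
                  names(pv$truth$true_v)[pv$truth$support_z])
})

test_that("sparse CCA with inactive budgets equals the cross-product SVD", {
  x <- random_view(10, 6, seed = 41)
  z <- random_view(10, 4, seed = 43)
  fit <- sparse_cca(x, z, n_components = 2L)
  K <- crossprod(scale(view_values(x)), scale(view_values(z))) / 9
  sv <- svd(K)
  for (k in 1:2) {
    expect_lt(diff_up_to_sign(fit$u[, k], sv$u[, k]), 1e-8)
    expect_lt(diff_up_to_sign(fit$v[, k], sv$v[, k]), 1e-8)
    expect_equal(fit$d[k], sv$d[k], tolerance = 1e-8)
  }
})

test_that("deflation reconstructs the cross-product at full rank", {
  x <- random_view(12, 5, seed = 47)
  z <- random_view(12, 4, seed = 53)
  fit <- sparse_cca(x, z, n_components = 4L)
  K <- crossprod(scale(view_values(x)), scale(view_values(z))) / 11
  recon <- Reduce(`+`, lapply(1:4, function(k) {
    fit$d[k] * tcrossprod(fit$u[, k], fit$v[, k])
  }))
  expect_equal(unname(recon), unname(K), tolerance = 1e-7)
})

test_that("independent views give a null-band first canonical correlation", {
  x <- random_view(200, 3, seed = 59)
  z <- random_view(200, 3, seed = 61)
  fit <- sparse_cca(x, z, n_components = 1L)
  Xs <- scale(view_values(x)); Zs <- scale(view_values(z))
  null_cor <- withr::with_seed(67, {
    vapply(seq_len(1000), function(i) {
      K <- crossprod(Xs, Zs[sample(200), ]) / 199
      svd(K, nu = 0, nv = 0)$d[1]
    }, numeric(1))
  })
  expect_lte(fit$canonical_correlation[1],
             stats::quantile(null_cor, 0.975) * 1.2)
})

test_that("sparse CCA rejects mismatched samples", {
  x <- random_view(6, 4, seed = 71)
  z <- random_view(5, 3, seed = 73)
  expect_error(sparse_cca(x, z), "same samples")
})

test_that("classical CCA matches its oracles and invariances", {
  x <- random_view(50, 2, seed = 79)
  z <- random_view(50, 2, seed = 83)
  fit <- classical_cca(x, z)
  expect_true(all(diff(fit$correlations) <= 1e-12))
  expect_true(all(fit$correlations >= 0 & fit$correlations <= 1))
  # generalized-eigenproblem oracle
  expect_equal(fit$correlations,
               geneig_cca_correlations(view_values(x), view_values(z)),
               tolerance = 1e-10)
  # base-R cancor agreement
  expect_equal(fit$correlations,
               stats::cancor(view_values(x), view_values(z))$cor,
               tolerance = 1e-10)
  # invariance under invertible linear maps of one view
  A <- matrix(c(2, 1, -1, 3), 2, 2)
  xa <- as_view(view_values(x) %*% A)
  expect_equal(classical_cca(xa, z)$correlations, fit$correlations,
               tolerance = 1e-8)
  # canonical variates have unit variance
  expect_equal(unname(apply(fit$scores_x, 2, var)), c(1, 1),
               tolerance = 1e-10)
  # perfect correlation when z copies a column of x
  z1 <- as_view(view_values(x)[, 1, drop = FALSE], prefix = "g")
  expect_equal(classical_cca(x, z1)$correlations[1], 1, tolerance = 1e-10)
})

test_that("classical CCA reports infeasible dimensions explicitly", {
  x <- random_view(10, 6, seed = 89)
  z <- random_view(10, 5, seed = 97)
  expect_error(classical_cca(x, z), "infeasible")
  # singular within-view covariance
  M <- view_values(random_view(30, 2, seed = 101))
  xs <- as_view(unname(cbind(M, M[, 1] + M[, 2])))
  expect_error(classical_cca(xs, random_view(30, 2, seed = 103)), "singular")
})

test_that("sub-dimensional search finds a planted perfect subset", {
  withr::with_seed(107, {
    X <- matrix(rnorm(10 * 6), 10, 6)
    colnames(X) <- paste0("g", 1:6)
    Z <- cbind(z1 = X[, 1] + X[, 2] - X[, 3], z2 = X[, 1] - X[, 2])
  })
  res <- subdimensional_cca(as_view(X), as_view(Z, prefix = "z"), k = 3,
                            top_m = 5)
  expect_equal(res$subsets$feature_set[[1]], c("g1", "g2", "g3"))
  expect_equal(res$subsets$correlation[1], 1, tolerance = 1e-8)
  expect_equal(res$total_evaluated, choose(6, 3))
})

test_that("subset counting, warnings, and infeasibility guards hold", {
  x <- random_view(12, 5, seed = 109)
  z <- random_view(12, 2, seed = 113)
  res <- subdimensional_cca(x, z, k = 3, top_m = 20)
  expect_equal(res$total_evaluated, 10L)
  expect_equal(nrow(res$subsets), 10L)
  expect_true(all(diff(res$subsets$correlation) <= 1e-12))
  expect_error(subdimensional_cca(x, random_view(12, 10, seed = 127), k = 3),
               "infeasible")
  expect_warning(
    subdimensional_cca(random_view(30, 6, seed = 131),
                       random_view(30, 2, seed = 137), k = 5, top_m = 2),
    "recommended")
})

test_that("size-one subsets rank by the per-feature multiple correlation", {
  x <- random_view(25, 6, seed = 139)
  z <- random_view(25, 3, seed = 149)
  res <- subdimensional_cca(x, z, k = 1, top_m = 6)
  # independent oracle: multiple correlation of each x feature on Z via lm
  X <- view_values(x); Z <- view_values(z)
  r <- vapply(seq_len(6), function(j) {
    sqrt(summary(stats::lm(X[, j] ~ Z))$r.squared)
  }, numeric(1))
  ord <- order(-r)
  expect_equal(unlist(res$subsets$feature_set), colnames(X)[ord])
  expect_equal(res$subsets$correlation, r[ord], tolerance = 1e-10)
})

test_that("permutation penalty selection is seeded and sane", {
  pv <- simulate_views(sim_scenario(n_per_group = 6, p = 20, q = 15,
                                    support_x = 4, support_z = 4,
                                    effect = 3, seed = 151))
  one <- select_penalties(pv$x, pv$z, c1_grid = 2, c2_grid = 2, n_perm = 10)
  expect_equal(c(one$c1, one$c2), c(2, 2))
  sel1 <- select_penalties(pv$x, pv$z, c1_grid = c(1.5, 2.5, 4),
                           c2_grid = c(1.5, 2.5), n_perm = 12, seed = 9)
  sel2 <- select_penalties(pv$x, pv$z, c1_grid = c(1.5, 2.5, 4),
                           c2_grid = c(1.5, 2.5), n_perm = 12, seed = 9)
  expect_identical(sel1, sel2)
  expect_error(select_penalties(pv$x, pv$z, c1_grid = 2, c2_grid = 2,
                                n_perm = 5), "at least 10")
  # on a strong planted signal the selected budgets beat the permutation null
  pt <- cca_permutation_test(pv$x, pv$z, c1 = sel1$c1, c2 = sel1$c2,
                             n_perm = 99, seed = 5)
  expect_gt(pt$observed, stats::quantile(pt$perm, 0.95))
})

test_that("the sCCA permutation test detects signal and stays seeded", {
  pv <- simulate_views(sim_scenario(n_per_group = 6, p = 20, q = 15,
                                    support_x = 4, support_z = 4,
                                    effect = 3, noise_sd_x = 0.5,
                                    noise_sd_z = 0.5, seed = 157))
  pt <- cca_permutation_test(pv$x, pv$z, c1 = 2, c2 = 2, n_perm = 99,
                             seed = 3)
  expect_lte(pt$p_value, 0.05)
  pt2 <- cca_permutation_test(pv$x, pv$z, c1 = 2, c2 = 2, n_perm = 99,
                              seed = 3)
  expect_identical(pt, pt2)
})
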