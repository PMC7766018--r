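# Shared fixtures and independently written oracles. Oracles deliberately use
# different code paths (brute force, base-R reference implementations) from
# the package internals they check.

# Build a view tibble from a bare matrix.
as_view <- function(M, labels = NULL, prefix = "f") {
  n <- nrow(M)
  if (is.null(colnames(M))) colnames(M) <- paste0(prefix, seq_len(ncol(M)))
  out <- tibble::tibble(sample = sprintf("S%02d", seq_len(n)))
  if (!is.null(labels)) out$label <- labels
  dplyr::bind_cols(out, tibble::as_tibble(M, .name_repair = "minimal"))
}

random_view <- function(n, p, seed, labels = NULL, prefix = "f") {
  M <- withr::with_seed(seed, matrix(rnorm(n * p), n, p))
  as_view(M, labels = labels, prefix = prefix)
}

view_values <- function(v) {
  as.matrix(v[setdiff(names(v), c("sample", "label"))])
}

# Largest absolute difference between two vectors identified up to sign.
diff_up_to_sign <- function(a, b) {
  min(max(abs(a - b)), max(abs(a + b)))
}

# Brute-force Benjamini-Hochberg: definitional min-over-tail of p * m / rank.
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (k in seq_len(m)) {
    q_sorted[k] <- min(1, min(p[o][k:m] * m / (k:m)))
  }
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# Independent exhaustive enumerator for the sub-dimensional search, built on
# stats::cancor rather than the package's whitening path.
cancor_enumerator <- function(x_view, z_view, k) {
  X <- view_values(x_view)
  Z <- view_values(z_view)
  cmb <- utils::combn(ncol(X), k)
  rho <- apply(cmb, 2, function(S) stats::cancor(X[, S], Z)$cor[1])
  ord <- order(-rho, seq_along(rho))
  list(
    features = apply(cmb[, ord, drop = FALSE], 2,
                     function(S) paste(colnames(X)[S], collapse = ";")),
    correlation = rho[ord])
}

# Generalized-eigenproblem CCA oracle (explicit solve, no whitening).
geneig_cca_correlations <- function(X, Z) {
  Xc <- scale(X, scale = FALSE)
  Zc <- scale(Z, scale = FALSE)
  n <- nrow(Xc)
  Sxx <- crossprod(Xc) / (n - 1)
  Szz <- crossprod(Zc) / (n - 1)
  Sxz <- crossprod(Xc, Zc) / (n - 1)
  M <- solve(Sxx, Sxz) %*% solve(Szz, t(Sxz))
  sqrt(pmax(sort(Re(eigen(M)$values), decreasing = TRUE), 0))
}
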