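# A "view" is a tidy sample-by-feature table: one row per sample, a sample
# identifier column, an optional two-level phenotype label column, and all
# remaining columns numeric features. Every user-facing function takes such a
# tibble first and returns one (or a fitted object carrying tidy() methods).

# Split a view tibble into a numeric matrix plus metadata. Internal.
view_parts <- function(data, sample_col = "sample", label_col = "label") {
  if (!is.data.frame(data)) {
    stop("`data` must be a data frame (one row per sample)", call. = FALSE)
  }
  if (!sample_col %in% names(data)) {
    stop("sample column '", sample_col, "' not found in `data`", call. = FALSE)
  }
  feature_ids <- setdiff(names(data), c(sample_col, label_col))
  if (length(feature_ids) == 0L) {
    stop("`data` has no feature columns", call. = FALSE)
  }
  values <- as.matrix(data[feature_ids])
  if (!is.numeric(values)) {
    bad <- feature_ids[!vapply(data[feature_ids], is.numeric, logical(1))]
    stop("non-numeric feature columns: ", paste(head(bad, 5L), collapse = ", "),
         call. = FALSE)
  }
  storage.mode(values) <- "double"
  sample_ids <- as.character(data[[sample_col]])
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample identifiers", call. = FALSE)
  }
  rownames(values) <- sample_ids
  labels <- if (label_col %in% names(data)) data[[label_col]] else NULL
  list(values = values, sample_ids = sample_ids, feature_ids = feature_ids,
       labels = labels, sample_col = sample_col, label_col = label_col)
}

# Reassemble a view tibble from a (possibly transformed) matrix and the
# metadata captured by view_parts().
rebuild_view <- function(values, parts) {
  stopifnot(nrow(values) == length(parts$sample_ids))
  out <- tibble::tibble(!!parts$sample_col := parts$sample_ids)
  if (!is.null(parts$labels)) out[[parts$label_col]] <- parts$labels
  vals <- tibble::as_tibble(values, .name_repair = "minimal")
  dplyr::bind_cols(out, vals)
}

# Validate a two-level phenotype; returns a factor with stable level order.
check_two_groups <- function(labels, min_per_group = 1L) {
  if (is.null(labels)) {
    stop("a per-sample phenotype label is required but none was found",
         call. = FALSE)
  }
  f <- factor(labels)
  if (nlevels(f) != 2L) {
    stop("exactly two phenotype groups required, found ", nlevels(f),
         call. = FALSE)
  }
  if (any(table(f) < min_per_group)) {
    stop("each phenotype group needs at least ", min_per_group, " samples",
         call. = FALSE)
  }
  f
}

# Column standardization of a numeric matrix; zero-variance columns are set
# to exact zero and reported via the "constant" attribute.
standardize_matrix <- function(M) {
  n <- nrow(M)
  if (n < 2L) stop("standardization needs at least two samples", call. = FALSE)
  mu <- colMeans(M)
  S <- sweep(M, 2L, mu, "-")
  sds <- sqrt(colSums(S^2) / (n - 1))
  const <- sds < 1e-12
  S <- sweep(S, 2L, ifelse(const, 1, sds), "/")
  if (any(const)) S[, const] <- 0
  attr(S, "constant") <- colnames(M)[const]
  S
}

l2norm <- function(x) sqrt(sum(x^2))
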