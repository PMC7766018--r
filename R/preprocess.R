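# Preprocessing verbs for sample-by-feature views: log transform, quantile
# normalization, probe-to-gene collapsing, abundance filtering, gene-list
# subsetting and column standardization. All verbs are deterministic, take a
# view tibble first and return one, so they chain with the pipe.

#' Log-transform a view
#'
#' Elementwise `log(value + offset, base)`. Microarray intensities are assumed
#' positive, so the default offset is 0; the base is recorded by downstream
#' fold-change computations, hence configurable.
#'
#' @param data View tibble (see package overview): sample column, optional
#'   label column, numeric feature columns.
#' @param offset Nonnegative pseudo-value added before taking logs.
#' @param base Logarithm base (default 2).
#' @param sample_col,label_col Names of the identifier columns.
#' @return The transformed view tibble.
#' @export
log_transform <- function(data, offset = 0, base = 2,
                          sample_col = "sample", label_col = "label") {
  if (offset < 0) stop("`offset` must be nonnegative", call. = FALSE)
  parts <- view_parts(data, sample_col, label_col)
  M <- parts$values + offset
  if (any(M <= 0, na.rm = TRUE)) {
    idx <- which(M <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "log undefined: sample '%s', feature '%s' has value %g (offset %g)",
      parts$sample_ids[idx[1L]], parts$feature_ids[idx[2L]],
      parts$values[idx[1L], idx[2L]], offset), call. = FALSE)
  }
  rebuild_view(log(M, base = base), parts)
}

# Map one sample's values onto the reference distribution; ties receive the
# mean of the reference values across their tied ranks.
qn_map_row <- function(x, ref) {
  o <- order(x)
  s <- x[o]
  grp <- cumsum(c(TRUE, diff(s) != 0))
  gm <- vapply(split(ref, grp), mean, numeric(1))
  out <- numeric(length(x))
  out[o] <- gm[grp]
  out
}

#' Quantile-normalize a view across samples
#'
#' Forces every sample to share one distribution: the reference is the
#' across-sample mean of order statistics, and each sample's values are
#' replaced by the reference values at their within-sample ranks (tied values
#' get the mean of the reference over the tied ranks). Rank order within each
#' sample is preserved and the operation is idempotent.
#'
#' @inheritParams log_transform
#' @return The normalized view tibble.
#' @export
quantile_normalize <- function(data, sample_col = "sample",
                               label_col = "label") {
  parts <- view_parts(data, sample_col, label_col)
  M <- parts$values
  if (anyNA(M)) {
    stop("missing values present; imputation is out of scope, drop or fill ",
         "them before quantile normalization", call. = FALSE)
  }
  if (nrow(M) < 2L) stop("need at least two samples", call. = FALSE)
  sorted <- matrix(apply(M, 1L, sort), nrow = ncol(M))
  ref <- rowMeans(sorted)
  out <- t(apply(M, 1L, qn_map_row, ref = ref))
  dimnames(out) <- dimnames(M)
  rebuild_view(out, parts)
}

#' Collapse probe-level features to genes by the median
#'
#' Multiple microarray probes mapping to the same gene are summarized by their
#' within-sample median, the summary that is robust under quantile
#' normalization. Every probe present in the view must be mapped.
#'
#' @inheritParams log_transform
#' @param probe_map Data frame with columns `probe` and `gene`.
#' @return A gene-level view tibble; gene order follows first appearance of
#'   each gene among the probe columns.
#' @export
collapse_probes <- function(data, probe_map, sample_col = "sample",
                            label_col = "label") {
  if (!is.data.frame(probe_map) ||
      !all(c("probe", "gene") %in% names(probe_map))) {
    stop("`probe_map` must be a data frame with columns 'probe' and 'gene'",
         call. = FALSE)
  }
  parts <- view_parts(data, sample_col, label_col)
  map <- setNames(as.character(probe_map$gene), as.character(probe_map$probe))
  unmapped <- setdiff(parts$feature_ids, names(map))
  if (length(unmapped) > 0L) {
    stop("unmapped probes: ", paste(head(unmapped, 10L), collapse = ", "),
         if (length(unmapped) > 10L) sprintf(" (and %d more)",
                                             length(unmapped) - 10L),
         call. = FALSE)
  }
  genes <- unname(map[parts$feature_ids])
  ugenes <- unique(genes)
  out <- vapply(ugenes, function(g) {
    cols <- parts$values[, genes == g, drop = FALSE]
    apply(cols, 1L, median)
  }, numeric(nrow(parts$values)))
  out <- matrix(out, nrow = nrow(parts$values),
                dimnames = list(parts$sample_ids, ugenes))
  parts$feature_ids <- ugenes
  rebuild_view(out, parts)
}

#' Filter low-abundance features
#'
#' Quality-control filter for abundance views (e.g. SEED Level2 categories):
#' keeps features detected (value > 0) in at least `min_prevalence` of the
#' samples and with total abundance at least `min_total`. The per-feature
#' report is attached as attribute `"filter_report"`.
#'
#' @inheritParams log_transform
#' @param min_prevalence Minimum detection fraction across samples, in
#'   \[0, 1\].
#' @param min_total Minimum total abundance summed over samples.
#' @return The filtered view tibble with a `"filter_report"` attribute
#'   (tibble: feature, prevalence, total, retained).
#' @export
filter_features <- function(data, min_prevalence = 0.25, min_total = 0,
                            sample_col = "sample", label_col = "label") {
  parts <- view_parts(data, sample_col, label_col)
  M <- parts$values
  if (any(M < 0, na.rm = TRUE)) {
    stop("abundances must be nonnegative", call. = FALSE)
  }
  prevalence <- colMeans(M > 0)
  total <- colSums(M)
  keep <- prevalence >= min_prevalence & total >= min_total
  report <- tibble::tibble(feature = parts$feature_ids,
                           prevalence = unname(prevalence),
                           total = unname(total), retained = unname(keep))
  if (!any(keep)) {
    stop("filter removed every feature; lower `min_prevalence`/`min_total`",
         call. = FALSE)
  }
  parts$feature_ids <- parts$feature_ids[keep]
  out <- rebuild_view(M[, keep, drop = FALSE], parts)
  attr(out, "filter_report") <- report
  out
}

#' Subset a view to a prior-knowledge gene list
#'
#' Restricts the feature columns to the symbols in `genes`. Symbols are
#' matched case-insensitively after trimming whitespace (microarray
#' annotations are inconsistent about case). List symbols absent from the
#' view are reported via the `"missing_symbols"` attribute.
#'
#' @inheritParams log_transform
#' @param genes Character vector of gene symbols (a prior-knowledge list).
#' @return The subsetted view tibble, feature order as in the original view,
#'   with attribute `"missing_symbols"`.
#' @export
subset_genes <- function(data, genes, sample_col = "sample",
                         label_col = "label") {
  if (!is.character(genes) || length(genes) == 0L) {
    stop("`genes` must be a non-empty character vector", call. = FALSE)
  }
  parts <- view_parts(data, sample_col, label_col)
  key <- function(x) tolower(trimws(x))
  genes <- genes[!duplicated(key(genes))]
  hit <- key(parts$feature_ids) %in% key(genes)
  if (!any(hit)) {
    stop("none of the ", length(genes),
         " list symbols are present in the view", call. = FALSE)
  }
  missing <- genes[!key(genes) %in% key(parts$feature_ids)]
  parts$feature_ids <- parts$feature_ids[hit]
  out <- rebuild_view(parts$values[, hit, drop = FALSE], parts)
  attr(out, "missing_symbols") <- missing
  out
}

#' Standardize feature columns
#'
#' Centers every feature to mean zero and scales features with positive
#' variance to unit standard deviation. Zero-variance features are set to
#' all-zero and listed in the `"constant_features"` attribute. Required before
#' the cross-product based sparse CCA so that component scores are
#' correlations.
#'
#' @inheritParams log_transform
#' @return The standardized view tibble with attribute `"constant_features"`.
#' @export
standardize_features <- function(data, sample_col = "sample",
                                 label_col = "label") {
  parts <- view_parts(data, sample_col, label_col)
  S <- standardize_matrix(parts$values)
  out <- rebuild_view(S, parts)
  attr(out, "constant_features") <- attr(S, "constant")
  out
}
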