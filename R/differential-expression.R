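# Univariate two-group differential expression: the "traditional" comparator
# to the multivariate analyses. Per-feature Welch t with Satterthwaite
# degrees of freedom, Benjamini-Hochberg FDR, and linear-scale fold changes
# (group-mean ratios after de-logging, matching how microarray fold changes
# are reported).

# Vectorized Welch statistics over feature columns. stats::t.test is the
# per-feature oracle in the test suite.
welch_columns <- function(M, groups) {
  f <- check_two_groups(groups, min_per_group = 2L)
  g1 <- f == levels(f)[1L]
  n1 <- sum(g1); n2 <- sum(!g1)
  M1 <- M[g1, , drop = FALSE]
  M2 <- M[!g1, , drop = FALSE]
  m1 <- colMeans(M1); m2 <- colMeans(M2)
  v1 <- colSums(sweep(M1, 2L, m1, "-")^2) / (n1 - 1)
  v2 <- colSums(sweep(M2, 2L, m2, "-")^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  # both groups constant: identical means define t = 0, p = 1
  degenerate <- se2 == 0
  if (any(degenerate)) {
    eq <- degenerate & (m1 == m2)
    t_stat[eq] <- 0
    df[eq] <- n1 + n2 - 2
    ne <- degenerate & (m1 != m2)
    t_stat[ne] <- sign(m1[ne] - m2[ne]) * Inf
    df[ne] <- n1 + n2 - 2
  }
  p <- 2 * pt(-abs(t_stat), df)
  list(mean_1 = m1, mean_2 = m2, t = t_stat, df = df, p = p,
       group_levels = levels(f))
}

#' Per-feature Welch t-tests
#'
#' Two-sided Welch (unequal-variance) t-test of every feature between the two
#' phenotype groups, with Satterthwaite degrees of freedom. A feature that is
#' constant in both groups with identical means yields `t = 0, p = 1`.
#'
#' @inheritParams log_transform
#' @return Tibble with columns `feature`, `mean_1`, `mean_2` (group means, in
#'   the order of the factor levels of the label), `t`, `df`, `p`.
#' @export
welch_t_test <- function(data, sample_col = "sample", label_col = "label") {
  parts <- view_parts(data, sample_col, label_col)
  w <- welch_columns(parts$values, parts$labels)
  tibble::tibble(feature = parts$feature_ids,
                 mean_1 = unname(w$mean_1), mean_2 = unname(w$mean_2),
                 t = unname(w$t), df = unname(w$df), p = unname(w$p))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR-adjusted p-values (q-values), order-preserving and capped at
#' 1. Thin validating wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("`p` must be numeric with all values in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Linear-scale fold changes
#'
#' Ratio of linear-scale group means per feature. If the view holds
#' log-transformed values (the usual case after preprocessing), they are
#' de-logged with the recorded base and offset before averaging, so the
#' reported magnitudes are linear-scale ratios. A zero denominator yields
#' `NA` (undefined), never infinity.
#'
#' @inheritParams log_transform
#' @param values_are_log Are the stored values on the log scale?
#' @param log_base,log_offset Base and offset recorded from
#'   [log_transform()]; ignored when `values_are_log = FALSE`.
#' @return Tibble with columns `feature`, `mean_1`, `mean_2` (linear scale)
#'   and `fold_change = mean_1 / mean_2`.
#' @export
fold_change <- function(data, values_are_log = TRUE, log_base = 2,
                        log_offset = 0, sample_col = "sample",
                        label_col = "label") {
  parts <- view_parts(data, sample_col, label_col)
  M <- parts$values
  if (values_are_log) M <- log_base^M - log_offset
  f <- check_two_groups(parts$labels, min_per_group = 1L)
  g1 <- f == levels(f)[1L]
  m1 <- colMeans(M[g1, , drop = FALSE])
  m2 <- colMeans(M[!g1, , drop = FALSE])
  fc <- ifelse(m2 == 0, NA_real_, m1 / m2)
  tibble::tibble(feature = parts$feature_ids, mean_1 = unname(m1),
                 mean_2 = unname(m2), fold_change = unname(fc))
}

#' Differential expression table
#'
#' Runs the full univariate pipeline on one view: per-feature Welch t-tests,
#' Benjamini-Hochberg q-values, and linear-scale fold changes, sorted by q
#' then p. Group 1 is the first factor level of the label (so with the
#' default BF/FF phenotypes the fold change is mean BF over mean FF).
#'
#' @inheritParams fold_change
#' @return Tibble with columns `feature`, `mean_1`, `mean_2` (linear-scale
#'   group means), `fold_change`, `t`, `df`, `p`, `q`, sorted by `q` then
#'   `p`. The statistic used is recorded in the `"method"` attribute.
#' @export
de_test <- function(data, values_are_log = TRUE, log_base = 2,
                    log_offset = 0, sample_col = "sample",
                    label_col = "label") {
  tt <- welch_t_test(data, sample_col = sample_col, label_col = label_col)
  fc <- fold_change(data, values_are_log = values_are_log,
                    log_base = log_base, log_offset = log_offset,
                    sample_col = sample_col, label_col = label_col)
  out <- dplyr::left_join(
    dplyr::select(fc, "feature", "mean_1", "mean_2", "fold_change"),
    dplyr::select(tt, "feature", "t", "df", "p"),
    by = "feature")
  out$q <- bh_adjust(out$p)
  out <- dplyr::arrange(out, .data$q, .data$p)
  attr(out, "method") <- "Welch t (Satterthwaite df), two-sided, BH FDR"
  out
}
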