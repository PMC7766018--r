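# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' Tidy a sparse PCA fit
#'
#' @param x A `sparse_pca` object.
#' @param matrix Which quantity to return: `"loadings"` (feature, component,
#'   loading), `"scores"` (sample, label, component, score) or
#'   `"membership"` (component, feature; non-zero loadings only).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sparse_pca <- function(x, matrix = c("loadings", "scores", "membership"),
                            ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    loadings = tidyr::pivot_longer(
      tibble::as_tibble(x$loadings, rownames = "feature"),
      -"feature", names_to = "component", values_to = "loading"),
    scores = {
      tb <- tibble::as_tibble(x$scores, rownames = "sample")
      if (!is.null(x$labels)) tb$label <- x$labels
      tidyr::pivot_longer(tb,
                          -dplyr::any_of(c("sample", "label")),
                          names_to = "component", values_to = "score")
    },
    membership = purrr::imap_dfr(x$membership, function(feats, k) {
      tibble::tibble(component = paste0("comp", k), feature = feats)
    }))
}

#' @rdname tidy.sparse_pca
#' @export
glance.sparse_pca <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores), n_features = nrow(x$loadings),
    n_components = x$n_components, penalty = x$penalty,
    membership_total = length(unique(unlist(x$membership))),
    converged = all(x$converged))
}

#' Tidy a sparse CCA fit
#'
#' @param x A `sparse_cca` object.
#' @param matrix `"loadings"`, `"scores"` or `"membership"`; all carry a
#'   `view` column ("x" or "z").
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sparse_cca <- function(x, matrix = c("loadings", "scores", "membership"),
                            ...) {
  matrix <- match.arg(matrix)
  long_load <- function(L, view) {
    dplyr::mutate(tidyr::pivot_longer(
      tibble::as_tibble(L, rownames = "feature"),
      -"feature", names_to = "component", values_to = "loading"),
      view = view, .before = 1L)
  }
  long_scores <- function(S, view) {
    tb <- tibble::as_tibble(S, rownames = "sample")
    if (!is.null(x$labels)) tb$label <- x$labels
    dplyr::mutate(tidyr::pivot_longer(tb,
                                      -dplyr::any_of(c("sample", "label")),
                                      names_to = "component",
                                      values_to = "score"),
                  view = view, .before = 1L)
  }
  switch(matrix,
    loadings = dplyr::bind_rows(long_load(x$u, "x"), long_load(x$v, "z")),
    scores = dplyr::bind_rows(long_scores(x$scores_x, "x"),
                              long_scores(x$scores_z, "z")),
    membership = dplyr::bind_rows(
      purrr::imap_dfr(x$membership_x, function(f, k) {
        tibble::tibble(view = "x", component = paste0("comp", k), feature = f)
      }),
      purrr::imap_dfr(x$membership_z, function(f, k) {
        tibble::tibble(view = "z", component = paste0("comp", k), feature = f)
      })))
}

#' @rdname tidy.sparse_cca
#' @export
glance.sparse_cca <- function(x, ...) {
  cc <- setNames(as.list(x$canonical_correlation),
                 paste0("cancor_comp", seq_len(x$n_components)))
  dplyr::bind_cols(
    tibble::tibble(n_samples = length(x$sample_ids),
                   p = nrow(x$u), q = nrow(x$v),
                   n_components = x$n_components, c1 = x$c1, c2 = x$c2),
    tibble::as_tibble(cc),
    tibble::tibble(converged = all(x$converged)))
}

#' Tidy a classical CCA fit
#'
#' @param x A `classical_cca` object.
#' @param ... Unused.
#' @return Tibble of canonical correlations per component.
#' @export
tidy.classical_cca <- function(x, ...) {
  tibble::tibble(component = comp_names(length(x$correlations)),
                 correlation = x$correlations)
}

#' @rdname tidy.classical_cca
#' @export
glance.classical_cca <- function(x, ...) {
  tibble::tibble(n = x$n, p = x$p, q = x$q,
                 first_correlation = x$correlations[1L])
}

#' Tidy a sub-dimensional CCA search
#'
#' @param x A `subcca` object.
#' @param ... Unused.
#' @return The ranked subset tibble (rank, features, correlation).
#' @export
tidy.subcca <- function(x, ...) {
  dplyr::select(x$subsets, "rank", "features", "correlation")
}

#' @rdname tidy.subcca
#' @export
glance.subcca <- function(x, ...) {
  tibble::tibble(k = x$k, total_evaluated = x$total_evaluated,
                 best_correlation = x$subsets$correlation[1L])
}

score_plot <- function(S, labels, colour = NULL, colour_name = "colour",
                       title = NULL) {
  if (ncol(S) < 2L) {
    stop("score plots need at least two components", call. = FALSE)
  }
  df <- tibble::tibble(comp1 = S[, 1L], comp2 = S[, 2L])
  if (!is.null(labels)) df$label <- as.factor(labels)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$comp1, y = .data$comp2))
  if (!is.null(colour)) {
    df$colour <- colour
    gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$comp1, y = .data$comp2,
                                           colour = .data$colour)) +
      ggplot2::scale_colour_viridis_c(name = colour_name)
  }
  if (!is.null(labels)) {
    gg <- gg + ggplot2::geom_point(ggplot2::aes(shape = .data$label), size = 3)
  } else {
    gg <- gg + ggplot2::geom_point(size = 3)
  }
  gg + ggplot2::labs(x = "component 1 score", y = "component 2 score",
                     title = title) +
    ggplot2::theme_minimal()
}

#' Plot sparse PCA scores
#'
#' First against second component scores, one point per sample, phenotype as
#' shape/colour.
#'
#' @param object A `sparse_pca` fit.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sparse_pca <- function(object, ...) {
  S <- object$scores
  if (ncol(S) < 2L) {
    stop("score plots need at least two components", call. = FALSE)
  }
  df <- tibble::tibble(comp1 = S[, 1L], comp2 = S[, 2L])
  if (!is.null(object$labels)) {
    df$label <- as.factor(object$labels)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$comp1, y = .data$comp2,
                                     colour = .data$label,
                                     shape = .data$label)) +
      ggplot2::geom_point(size = 3) +
      ggplot2::labs(x = "component 1 score", y = "component 2 score",
                    title = "Sparse PCA sample scores") +
      ggplot2::theme_minimal()
  } else {
    score_plot(S, NULL, title = "Sparse PCA sample scores")
  }
}

#' Plot sparse CCA scores
#'
#' First against second component scores of one view; by default points are
#' coloured by the opposite view's first-component score, making cross-view
#' agreement visible in a single panel.
#'
#' @param object A `sparse_cca` fit.
#' @param view Which view's scores form the axes: `"x"` or `"z"`.
#' @param colour `"opposite"` (default) or `"label"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sparse_cca <- function(object, view = c("x", "z"),
                                colour = c("opposite", "label"), ...) {
  view <- match.arg(view)
  colour <- match.arg(colour)
  S <- if (view == "x") object$scores_x else object$scores_z
  opp <- if (view == "x") object$scores_z else object$scores_x
  if (colour == "opposite") {
    score_plot(S, object$labels, colour = opp[, 1L],
               colour_name = sprintf("%s comp1 score",
                                     if (view == "x") "z" else "x"),
               title = sprintf("Sparse CCA scores (%s view)", view))
  } else {
    score_plot(S, object$labels,
               title = sprintf("Sparse CCA scores (%s view)", view))
  }
}
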