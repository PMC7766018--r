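# Synthetic paired-view generator. Emulates the infant feeding study design:
# two views measured on the same n = 12 stool samples (6 breast-fed, 6
# formula-fed), host gene expression on one side and SEED Level2 microbial
# functional-category abundances on the other, with an optional sparse latent
# factor shared across views and tied to the feeding phenotype.

#' Define a paired-view simulation scenario
#'
#' A scenario fixes the sample size, view dimensions, planted sparse supports,
#' latent phenotype effect and noise levels for [simulate_views()]. The latent
#' factor for sample \eqn{i} is \eqn{t_i = \mathrm{effect} \cdot
#' 1\{\mathrm{label}_i = \mathrm{BF}\} + \epsilon_i} with standard normal
#' \eqn{\epsilon_i}; the expression view is \eqn{X = t w^\top + \sigma_x E}
#' where the planted weight \eqn{w} carries `±amplitude` on each of the
#' `support_x` loaded features (its unit-norm direction is recorded as the
#' true loading), and the abundance view analogously through \eqn{v}
#' (optionally mapped through an exponential link and per-sample total
#' normalization to mimic relative abundances).
#'
#' @param n_per_group Samples per phenotype group (>= 2).
#' @param p,q Number of features in the expression (X) and abundance (Z) view.
#' @param support_x,support_z Number of truly loaded features per view.
#' @param effect Latent mean separation between the phenotypes, in units of
#'   the latent factor's residual standard deviation. 0 means no phenotype
#'   signal.
#' @param amplitude Per-feature loading amplitude: every truly loaded feature
#'   carries the latent factor scaled by `±amplitude`, so its effect size is
#'   interpretable per feature and independent of the support size. The truth
#'   record stores the unit-norm loading direction.
#' @param noise_sd_x,noise_sd_z Gaussian noise standard deviations.
#' @param count_model_z If `TRUE`, Z is built on the log scale, passed through
#'   an exponential link and renormalized to per-sample relative abundances.
#' @param shared_factor If `TRUE` (default) both views load on the same latent
#'   factor, so cross-view correlative structure exists; if `FALSE` each view
#'   gets an independent factor, emulating data where sparse CCA should find
#'   no mutual structure.
#' @param seed Integer seed; generation is fully deterministic given the
#'   scenario.
#' @return An object of class `sim_scenario`.
#' @seealso [study_scenario()] for the study-shaped presets,
#'   [simulate_views()] to generate data.
#' @export
sim_scenario <- function(n_per_group = 6, p = 72, q = 115,
                         support_x = 10, support_z = 10,
                         effect = 3, amplitude = 1,
                         noise_sd_x = 1, noise_sd_z = 1,
                         count_model_z = FALSE, shared_factor = TRUE,
                         seed = 1L) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
      stop("`", nm, "` must be a single number", call. = FALSE)
    }
    x
  }
  n_per_group <- num1(n_per_group, "n_per_group")
  p <- num1(p, "p"); q <- num1(q, "q")
  support_x <- num1(support_x, "support_x")
  support_z <- num1(support_z, "support_z")
  effect <- num1(effect, "effect")
  amplitude <- num1(amplitude, "amplitude")
  noise_sd_x <- num1(noise_sd_x, "noise_sd_x")
  noise_sd_z <- num1(noise_sd_z, "noise_sd_z")
  if (n_per_group < 2) stop("`n_per_group` must be at least 2", call. = FALSE)
  if (p < 1 || q < 1) stop("view dimensions must be positive", call. = FALSE)
  if (support_x < 1 || support_x > p) {
    stop("`support_x` must lie in [1, p]", call. = FALSE)
  }
  if (support_z < 1 || support_z > q) {
    stop("`support_z` must lie in [1, q]", call. = FALSE)
  }
  if (effect < 0) stop("`effect` must be nonnegative", call. = FALSE)
  if (amplitude <= 0) stop("`amplitude` must be positive", call. = FALSE)
  if (noise_sd_x < 0 || noise_sd_z < 0) {
    stop("noise standard deviations must be nonnegative", call. = FALSE)
  }
  structure(
    list(n_per_group = as.integer(n_per_group), p = as.integer(p),
         q = as.integer(q), support_x = as.integer(support_x),
         support_z = as.integer(support_z), effect = effect,
         amplitude = amplitude, noise_sd_x = noise_sd_x, noise_sd_z = noise_sd_z,
         count_model_z = isTRUE(count_model_z),
         shared_factor = isTRUE(shared_factor), seed = as.integer(seed)),
    class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("Paired-view simulation scenario\n")
  cat(sprintf("  samples: %d per group (total %d)\n",
              x$n_per_group, 2L * x$n_per_group))
  cat(sprintf("  X: %d features, support %d;  Z: %d features, support %d\n",
              x$p, x$support_x, x$q, x$support_z))
  cat(sprintf("  effect %.3g, amplitude %.3g, noise (%.3g, %.3g), %s factor%s, seed %d\n",
              x$effect, x$amplitude, x$noise_sd_x, x$noise_sd_z,
              if (x$shared_factor) "shared" else "independent",
              if (x$count_model_z) ", count-link Z" else "", x$seed))
  invisible(x)
}

#' Study-shaped scenario presets
#'
#' Returns a scenario matching the shape of the infant feeding study: 12
#' samples (6 breast-fed, 6 formula-fed), 115 SEED Level2 microbial categories,
#' and a host gene list of 72 (SCFA receptor signaling), 811 (immunity and
#' defense) or 52 (intestinal barrier function) genes.
#'
#' @param list_name One of `"scfa"`, `"immune"`, `"barrier"`.
#' @param ... Further arguments passed to [sim_scenario()] (effect, noise,
#'   supports, seed, ...).
#' @return A `sim_scenario` with `n_per_group = 6`, `q = 115` and `p` equal to
#'   the named gene-list size.
#' @export
study_scenario <- function(list_name = c("scfa", "immune", "barrier"), ...) {
  if (length(list_name) == 1L && !list_name %in% c("scfa", "immune", "barrier")) {
    stop("unknown gene list '", list_name,
         "'; expected one of scfa, immune, barrier", call. = FALSE)
  }
  list_name <- match.arg(list_name)
  p <- c(scfa = 72L, immune = 811L, barrier = 52L)[[list_name]]
  sim_scenario(n_per_group = 6, p = p, q = 115, ...)
}

# Sparse unit-norm loading on the first `support` features, alternating signs
# so planted truth is predictable in tests.
planted_loading <- function(n_features, support, prefix) {
  w <- numeric(n_features)
  w[seq_len(support)] <- rep_len(c(1, -1), support) / sqrt(support)
  names(w) <- paste0(prefix, sprintf("%04d", seq_len(n_features)))
  w
}

#' Generate a paired two-view dataset
#'
#' Draws one dataset from a [sim_scenario()]: a host-expression-like view `x`,
#' an abundance-like view `z`, and the ground truth (latent scores, planted
#' loadings, supports). Output is bit-reproducible given the scenario seed.
#'
#' @param scenario A `sim_scenario`.
#' @return An object of class `paired_views`: a list with tibbles `x` and `z`
#'   (columns `sample`, `label`, then features) and `truth`, a list holding
#'   `latent` (tibble of per-sample factor scores), named numeric vectors
#'   `true_u`, `true_v`, integer vectors `support_x`, `support_z`, and the
#'   scenario itself.
#' @examples
#' pv <- simulate_views(sim_scenario(n_per_group = 3, p = 8, q = 6,
#'                                   support_x = 3, support_z = 2, seed = 42))
#' pv$x
#' @export
simulate_views <- function(scenario) {
  if (!inherits(scenario, "sim_scenario")) {
    stop("`scenario` must be created by sim_scenario()", call. = FALSE)
  }
  n <- 2L * scenario$n_per_group
  labels <- rep(c("BF", "FF"), each = scenario$n_per_group)
  sample_ids <- sprintf("S%02d", seq_len(n))
  true_u <- planted_loading(scenario$p, scenario$support_x, "gene")
  true_v <- planted_loading(scenario$q, scenario$support_z, "seed2cat")

  withr::with_seed(scenario$seed, {
    t_x <- scenario$effect * (labels == "BF") + rnorm(n)
    t_z <- if (scenario$shared_factor) {
      t_x
    } else {
      scenario$effect * (labels == "BF") + rnorm(n)
    }
    w_x <- scenario$amplitude * sqrt(scenario$support_x) * true_u
    w_z <- scenario$amplitude * sqrt(scenario$support_z) * true_v
    X <- tcrossprod(t_x, w_x) +
      scenario$noise_sd_x * matrix(rnorm(n * scenario$p), n, scenario$p)
    Zlin <- tcrossprod(t_z, w_z) +
      scenario$noise_sd_z * matrix(rnorm(n * scenario$q), n, scenario$q)
  })
  if (scenario$count_model_z) {
    A <- exp(Zlin)
    Z <- A / rowSums(A)
  } else {
    Z <- Zlin
  }
  colnames(X) <- names(true_u)
  colnames(Z) <- names(true_v)
  rownames(X) <- rownames(Z) <- sample_ids

  as_view <- function(M) {
    dplyr::bind_cols(tibble::tibble(sample = sample_ids, label = labels),
                     tibble::as_tibble(M, .name_repair = "minimal"))
  }
  structure(
    list(x = as_view(X), z = as_view(Z),
         truth = list(
           latent = tibble::tibble(sample = sample_ids, label = labels,
                                   score_x = t_x, score_z = t_z),
           true_u = true_u, true_v = true_v,
           support_x = seq_len(scenario$support_x),
           support_z = seq_len(scenario$support_z),
           scenario = scenario)),
    class = "paired_views")
}

#' @export
print.paired_views <- function(x, ...) {
  sc <- x$truth$scenario
  cat(sprintf("Paired views: %d samples; X %d features, Z %d features\n",
              nrow(x$x), sc$p, sc$q))
  cat(sprintf("  planted supports %d / %d, effect %.3g, %s factor\n",
              sc$support_x, sc$support_z, sc$effect,
              if (sc$shared_factor) "shared" else "independent"))
  invisible(x)
}

#' Write a paired-view dataset to TSV files
#'
#' Writes `x.tsv`, `z.tsv` (samples in rows, first column `sample`, header row
#' of feature IDs), `labels.tsv`, `truth_loadings.tsv`, `truth_latent.tsv` and
#' `scenario.yaml` into `dir`.
#'
#' @param views A `paired_views` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_paired_views <- function(views, dir) {
  stopifnot(inherits(views, "paired_views"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    x = file.path(dir, "x.tsv"), z = file.path(dir, "z.tsv"),
    labels = file.path(dir, "labels.tsv"),
    loadings = file.path(dir, "truth_loadings.tsv"),
    latent = file.path(dir, "truth_latent.tsv"),
    scenario = file.path(dir, "scenario.yaml"))
  readr::write_tsv(dplyr::select(views$x, -"label"), paths[["x"]])
  readr::write_tsv(dplyr::select(views$z, -"label"), paths[["z"]])
  readr::write_tsv(dplyr::distinct(views$x[c("sample", "label")]),
                   paths[["labels"]])
  tr <- views$truth
  loadings <- dplyr::bind_rows(
    tibble::tibble(view = "x", feature = names(tr$true_u),
                   loading = unname(tr$true_u)),
    tibble::tibble(view = "z", feature = names(tr$true_v),
                   loading = unname(tr$true_v)))
  readr::write_tsv(loadings, paths[["loadings"]])
  readr::write_tsv(tr$latent, paths[["latent"]])
  write_scenario_yaml(tr$scenario, paths[["scenario"]])
  invisible(paths)
}
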