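# End-to-end pipeline wrappers tying the stages together the way the study
# workflow runs them: preprocess -> subset -> sPCA / sCCA / sub-dimensional
# CCA -> DE -> simulate. Each wrapper takes a run configuration (a list, or a
# YAML file path), writes TSV results plus a machine-readable provenance
# record into the output directory, and returns its results invisibly.
# Rendered plots are side effects only; nothing downstream depends on them.

#' Build a run configuration
#'
#' Collects input paths and options for [run_preprocess()], [run_analyze()]
#' and [run_simulate()]. Referenced paths are validated at construction, so a
#' missing input fails before any compute.
#'
#' @param x,z Paths to the expression (X) and abundance (Z) view TSVs
#'   (`z` optional for X-only analyses).
#' @param labels Path to the sample-label TSV (columns `sample`, `label`).
#' @param gene_list,probe_map Optional paths to a prior-knowledge gene list
#'   and a probe-to-gene map.
#' @param out_dir Output directory (created when a pipeline runs).
#' @param log_offset,log_base Log-transform options.
#' @param min_prevalence,min_total Abundance-filter thresholds for Z.
#' @param skip Character vector of preprocessing stages to skip, among
#'   `c("log", "quantile", "collapse", "filter", "subset", "standardize")`.
#' @param penalty sPCA loading budget (`NULL`: inactive).
#' @param c1,c2 sCCA budgets (`NULL`: inactive).
#' @param n_components Components for sPCA/sCCA.
#' @param k,top_m Sub-dimensional search controls.
#' @param n_perm Permutations for the sCCA null calibration (0 to skip).
#' @param seed Seed recorded in every output.
#' @param plots Render score scatter plots (PDF side effects)?
#' @return A `run_config` list.
#' @export
run_config <- function(x, labels, z = NULL, gene_list = NULL,
                       probe_map = NULL, out_dir = "spcca-run",
                       log_offset = 0, log_base = 2, min_prevalence = 0.25,
                       min_total = 0, skip = character(),
                       penalty = NULL, c1 = NULL, c2 = NULL,
                       n_components = 2L, k = 3L, top_m = 10L,
                       n_perm = 199L, seed = 1L, plots = TRUE) {
  cfg <- list(x = x, z = z, labels = labels, gene_list = gene_list,
              probe_map = probe_map, out_dir = out_dir,
              log_offset = log_offset, log_base = log_base,
              min_prevalence = min_prevalence, min_total = min_total,
              skip = skip, penalty = penalty, c1 = c1, c2 = c2,
              n_components = as.integer(n_components), k = as.integer(k),
              top_m = as.integer(top_m), n_perm = as.integer(n_perm),
              seed = as.integer(seed), plots = isTRUE(plots))
  for (field in c("x", "z", "labels", "gene_list", "probe_map")) {
    pth <- cfg[[field]]
    if (!is.null(pth) && !file.exists(pth)) {
      stop("config input `", field, "` does not exist: ", pth, call. = FALSE)
    }
  }
  known <- c("log", "quantile", "collapse", "filter", "subset", "standardize")
  if (length(cfg$skip) > 0L && !all(cfg$skip %in% known)) {
    stop("unknown stage in `skip`; known stages: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path Path to a YAML file whose keys are [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  do.call(run_config, yaml::read_yaml(path))
}

as_run_config <- function(config) {
  if (inherits(config, "run_config")) return(config)
  if (is.character(config) && length(config) == 1L) {
    return(read_run_config(config))
  }
  if (is.list(config)) return(do.call(run_config, config))
  stop("`config` must be a run_config, a list, or a YAML path", call. = FALSE)
}

log_msg <- function(...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [spcca] ", ...)
}

write_provenance <- function(cfg, dir, command, extra = list()) {
  inputs <- Filter(Negate(is.null),
                   cfg[c("x", "z", "labels", "gene_list", "probe_map")])
  hashes <- vapply(inputs, function(p) unname(tools::md5sum(p)), character(1))
  record <- c(list(command = command,
                   package_version = as.character(packageVersion("spcca")),
                   seed = cfg$seed,
                   config = unclass(cfg)[!vapply(cfg, is.null, logical(1))],
                   input_md5 = as.list(hashes)),
              extra)
  jsonlite::write_json(record, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

ensure_dir <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dir
}

#' Preprocess raw views
#'
#' Applies the preprocessing chain in fixed stage order -- log transform,
#' quantile normalization, probe collapsing, abundance filtering, gene-list
#' subsetting, standardization -- with any stage skippable. Log/quantile/
#' collapse/subset apply to the expression view, the abundance filter to the
#' Z view, standardization to both. Writes `x_processed.tsv`,
#' `z_processed.tsv` (when Z is given), a per-stage feature-count
#' `preprocess_report.tsv` and `provenance.json` into the output directory.
#'
#' @param config A [run_config()], a plain list of its arguments, or a YAML
#'   path.
#' @return Invisibly, a list with the processed views and the stage report.
#' @export
run_preprocess <- function(config) {
  cfg <- as_run_config(config)
  dir <- ensure_dir(cfg$out_dir)
  run <- function(stage) !stage %in% cfg$skip
  report <- list()
  note <- function(stage, view, n_in, n_out) {
    report[[length(report) + 1L]] <<-
      tibble::tibble(stage = stage, view = view,
                     features_in = n_in, features_out = n_out)
  }
  n_feats <- function(v) ncol(v) - sum(c("sample", "label") %in% names(v))

  x <- read_view_tsv(cfg$x, labels_path = cfg$labels)
  log_msg("loaded X: ", nrow(x), " samples, ", n_feats(x), " features")
  if (run("log")) {
    n0 <- n_feats(x)
    x <- log_transform(x, offset = cfg$log_offset, base = cfg$log_base)
    note("log", "x", n0, n_feats(x))
  }
  if (run("quantile")) {
    n0 <- n_feats(x)
    x <- quantile_normalize(x)
    note("quantile", "x", n0, n_feats(x))
  }
  if (run("collapse") && !is.null(cfg$probe_map)) {
    n0 <- n_feats(x)
    x <- collapse_probes(x, read_probe_map(cfg$probe_map))
    note("collapse", "x", n0, n_feats(x))
  }
  if (run("subset") && !is.null(cfg$gene_list)) {
    n0 <- n_feats(x)
    x <- subset_genes(x, read_gene_list(cfg$gene_list))
    note("subset", "x", n0, n_feats(x))
  }
  if (run("standardize")) {
    n0 <- n_feats(x)
    x <- standardize_features(x)
    note("standardize", "x", n0, n_feats(x))
  }

  z <- NULL
  if (!is.null(cfg$z)) {
    z <- read_view_tsv(cfg$z, labels_path = cfg$labels)
    log_msg("loaded Z: ", nrow(z), " samples, ", n_feats(z), " features")
    if (run("filter")) {
      n0 <- n_feats(z)
      z <- filter_features(z, min_prevalence = cfg$min_prevalence,
                           min_total = cfg$min_total)
      note("filter", "z", n0, n_feats(z))
    }
    if (run("standardize")) {
      n0 <- n_feats(z)
      z <- standardize_features(z)
      note("standardize", "z", n0, n_feats(z))
    }
  }

  report <- dplyr::bind_rows(report)
  write_view_tsv(x, file.path(dir, "x_processed.tsv"))
  if (!is.null(z)) write_view_tsv(z, file.path(dir, "z_processed.tsv"))
  readr::write_tsv(report, file.path(dir, "preprocess_report.tsv"))
  write_provenance(cfg, dir, "preprocess")
  log_msg("preprocess done; outputs in ", dir)
  invisible(list(x = x, z = z, report = report))
}

write_loadings_tsv <- function(L, path, view = NULL) {
  tb <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(L, rownames = "feature")),
    -"feature", names_to = "component", values_to = "loading")
  if (!is.null(view)) tb <- dplyr::mutate(tb, view = view, .before = 1L)
  readr::write_tsv(tb, path)
}

write_scores_tsv <- function(S, labels, path) {
  tb <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(S, rownames = "sample"),
                  label = labels, .after = "sample"),
    -c("sample", "label"), names_to = "component", values_to = "score")
  readr::write_tsv(tb, path)
}

#' Run one analysis mode on processed views
#'
#' Dispatches to sparse PCA, sparse CCA, the sub-dimensional subset search,
#' or differential expression, and writes result tables, a metadata record
#' and (optionally) score scatter plots -- component 1 against component 2,
#' points labeled by phenotype; for sCCA the points are colored by the
#' opposite view's first-component score.
#'
#' @inheritParams run_preprocess
#' @param mode One of `"spca"`, `"scca"`, `"subcca"`, `"de"`.
#' @return Invisibly, the fitted object / result table.
#' @export
run_analyze <- function(config, mode = c("spca", "scca", "subcca", "de")) {
  mode <- match.arg(mode)
  cfg <- as_run_config(config)
  if (mode %in% c("scca", "subcca") && is.null(cfg$z)) {
    stop("mode '", mode, "' needs the Z view; set `z` in the config",
         call. = FALSE)
  }
  dir <- ensure_dir(file.path(cfg$out_dir, mode))
  x <- read_view_tsv(cfg$x, labels_path = cfg$labels)
  z <- if (!is.null(cfg$z)) read_view_tsv(cfg$z, labels_path = cfg$labels)
  meta <- list(mode = mode, seed = cfg$seed)

  result <- switch(
    mode,
    spca = {
      fit <- sparse_pca(x, penalty = cfg$penalty,
                        n_components = cfg$n_components)
      write_loadings_tsv(fit$loadings, file.path(dir, "loadings.tsv"))
      write_scores_tsv(fit$scores, fit$labels, file.path(dir, "scores.tsv"))
      readr::write_tsv(tidy(fit, "membership"),
                       file.path(dir, "membership.tsv"))
      meta$penalty <- fit$penalty
      meta$iterations <- fit$iterations
      meta$converged <- fit$converged
      meta$membership_sizes <- vapply(fit$membership, length, integer(1))
      if (cfg$plots) {
        ggplot2::ggsave(file.path(dir, "scores.pdf"), autoplot(fit),
                        width = 5, height = 4)
      }
      fit
    },
    scca = {
      fit <- sparse_cca(x, z, c1 = cfg$c1, c2 = cfg$c2,
                        n_components = cfg$n_components)
      write_loadings_tsv(fit$u, file.path(dir, "loadings_x.tsv"), "x")
      write_loadings_tsv(fit$v, file.path(dir, "loadings_z.tsv"), "z")
      write_scores_tsv(fit$scores_x, fit$labels,
                       file.path(dir, "scores_x.tsv"))
      write_scores_tsv(fit$scores_z, fit$labels,
                       file.path(dir, "scores_z.tsv"))
      meta$c1 <- fit$c1
      meta$c2 <- fit$c2
      meta$canonical_correlation <- fit$canonical_correlation
      meta$iterations <- fit$iterations
      meta$converged <- fit$converged
      if (cfg$n_perm > 0L) {
        pt <- cca_permutation_test(x, z, c1 = cfg$c1, c2 = cfg$c2,
                                   n_perm = cfg$n_perm, seed = cfg$seed)
        meta$permutation_p <- pt$p_value
        meta$permutation_null_mean <- mean(pt$perm)
      }
      if (cfg$plots) {
        ggplot2::ggsave(file.path(dir, "scores_x.pdf"),
                        autoplot(fit, view = "x"), width = 5, height = 4)
        ggplot2::ggsave(file.path(dir, "scores_z.pdf"),
                        autoplot(fit, view = "z"), width = 5, height = 4)
      }
      fit
    },
    subcca = {
      res <- subdimensional_cca(x, z, k = cfg$k, top_m = cfg$top_m)
      readr::write_tsv(
        dplyr::select(res$subsets, "rank", "features", "correlation"),
        file.path(dir, "subsets.tsv"))
      meta$k <- res$k
      meta$total_evaluated <- res$total_evaluated
      res
    },
    de = {
      tab <- de_test(x, log_base = cfg$log_base, log_offset = cfg$log_offset)
      readr::write_tsv(tab, file.path(dir, "de.tsv"))
      meta$statistic <- attr(tab, "method")
      meta$n_q05 <- sum(tab$q < 0.05)
      tab
    })

  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_provenance(cfg, dir, paste0("analyze --mode ", mode))
  log_msg("analyze (", mode, ") done; outputs in ", dir)
  invisible(result)
}

#' Run the comparative simulation study
#'
#' Wraps [run_comparison()] over a scenario grid (the default study-shaped
#' grid unless `scenarios` are supplied), writing the per-replicate table,
#' the per-cell summary and a rendered text summary.
#'
#' @inheritParams run_preprocess
#' @param scenarios Optional list of `sim_scenario` objects.
#' @param methods,replicates Passed to [run_comparison()].
#' @return Invisibly, list with `results` and `summary` tibbles.
#' @export
run_simulate <- function(config = list(x = NULL), scenarios = NULL,
                         methods = c("scca", "spca", "subcca"),
                         replicates = 50L) {
  cfg <- if (inherits(config, "run_config")) config else {
    # simulation needs no input files; accept a bare option list
    opts <- if (is.character(config)) yaml::read_yaml(config) else config
    structure(utils::modifyList(
      list(out_dir = "spcca-run", seed = 1L, k = 3L, top_m = 10L),
      Filter(Negate(is.null), opts)), class = "run_config")
  }
  dir <- ensure_dir(file.path(cfg$out_dir, "simulate"))
  if (is.null(scenarios)) scenarios <- default_scenario_grid()
  results <- run_comparison(scenarios, methods = methods,
                            replicates = replicates, seed = cfg$seed,
                            k = cfg$k, top_m = cfg$top_m)
  summary <- summarize_comparison(results)
  readr::write_tsv(results, file.path(dir, "comparison.tsv"))
  readr::write_tsv(summary, file.path(dir, "comparison_summary.tsv"))
  lines <- c(
    sprintf("Comparative simulation: %d scenarios x %d methods, %d replicates (seed %d)",
            length(scenarios), length(methods), replicates, cfg$seed),
    sprintf("grid cells: %d", length(scenarios) * length(methods)),
    "",
    utils::capture.output(print(as.data.frame(summary), row.names = FALSE)))
  writeLines(lines, file.path(dir, "summary.txt"))
  jsonlite::write_json(
    list(command = "simulate", seed = cfg$seed,
         n_scenarios = length(scenarios), methods = methods,
         replicates = replicates, grid_cells = length(scenarios) * length(methods),
         package_version = as.character(packageVersion("spcca"))),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, pretty = TRUE)
  log_msg("simulation done; outputs in ", dir)
  invisible(list(results = results, summary = summary))
}
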