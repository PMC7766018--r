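# End-to-end pipeline fixtures are generated in code: raw positive
# "intensities" for X (so the log stage applies) and nonnegative abundances
# for Z, written as TSV into a temp directory.

make_pipeline_fixture <- function(dir, effect = 3, seed = 212,
                                  shared_factor = TRUE) {
  pv <- simulate_views(sim_scenario(n_per_group = 6, p = 20, q = 15,
                                    support_x = 4, support_z = 4,
                                    effect = effect, seed = seed,
                                    shared_factor = shared_factor))
  raw_x <- pv$x
  raw_x[-(1:2)] <- 2^(raw_x[-(1:2)] / 2 + 8)    # positive intensities
  raw_z <- pv$z
  # nonnegative abundances on a linear scale (global shift)
  raw_z[-(1:2)] <- raw_z[-(1:2)] - min(raw_z[-(1:2)]) + 0.1
  readr::write_tsv(dplyr::select(raw_x, -"label"), file.path(dir, "x.tsv"))
  readr::write_tsv(dplyr::select(raw_z, -"label"), file.path(dir, "z.tsv"))
  readr::write_tsv(raw_x[c("sample", "label")], file.path(dir, "labels.tsv"))
  pv
}

test_that("the preprocessing pipeline runs, reports, and reruns byte-identically", {
  dir <- withr::local_tempdir()
  make_pipeline_fixture(dir)
  cfg <- run_config(x = file.path(dir, "x.tsv"), z = file.path(dir, "z.tsv"),
                    labels = file.path(dir, "labels.tsv"),
                    out_dir = file.path(dir, "out1"), min_prevalence = 0,
                    plots = FALSE)
  res <- suppressMessages(run_preprocess(cfg))
  expect_true(file.exists(file.path(dir, "out1", "x_processed.tsv")))
  expect_true(file.exists(file.path(dir, "out1", "provenance.json")))
  expect_setequal(res$report$stage,
                  c("log", "quantile", "filter", "standardize"))
  expect_true(all(res$report$features_in >= res$report$features_out))
  # standardized output
  expect_equal(unname(colMeans(view_values(res$x))), rep(0, 20),
               tolerance = 1e-10)

  cfg2 <- run_config(x = file.path(dir, "x.tsv"), z = file.path(dir, "z.tsv"),
                     labels = file.path(dir, "labels.tsv"),
                     out_dir = file.path(dir, "out2"), min_prevalence = 0,
                     plots = FALSE)
  suppressMessages(run_preprocess(cfg2))
  for (f in c("x_processed.tsv", "z_processed.tsv", "preprocess_report.tsv")) {
    expect_identical(readLines(file.path(dir, "out1", f)),
                     readLines(file.path(dir, "out2", f)))
  }
})

test_that("configuration validation fails before compute on missing inputs", {
  dir <- withr::local_tempdir()
  make_pipeline_fixture(dir)
  expect_error(run_config(x = file.path(dir, "x.tsv"),
                          labels = file.path(dir, "absent.tsv")),
               "labels.*does not exist")
  expect_error(run_config(x = file.path(dir, "x.tsv"),
                          labels = file.path(dir, "labels.tsv"),
                          skip = "normalize"), "unknown stage")
})

test_that("malformed matrices are rejected with a named column", {
  dir <- withr::local_tempdir()
  writeLines(c("sample\tg1\tg2", "S1\t1.0\t2.0", "S2\toops\t3.0"),
             file.path(dir, "bad.tsv"))
  expect_error(read_view_tsv(file.path(dir, "bad.tsv")), "g1")
})

test_that("analysis modes write results whose numbers reproduce the science", {
  dir <- withr::local_tempdir()
  pv <- make_pipeline_fixture(dir, effect = 3)
  # quantile normalization is skipped here: with only 20 features it would
  # equalize away most of the planted between-sample signal (it is meant for
  # probe-scale matrices); the preprocessing test above exercises it
  cfg <- run_config(x = file.path(dir, "x.tsv"), z = file.path(dir, "z.tsv"),
                    labels = file.path(dir, "labels.tsv"),
                    out_dir = file.path(dir, "out"), min_prevalence = 0,
                    skip = "quantile", penalty = 2, c1 = 2, c2 = 2,
                    n_perm = 49, plots = FALSE)
  suppressMessages(run_preprocess(cfg))
  proc <- run_config(x = file.path(dir, "out", "x_processed.tsv"),
                     z = file.path(dir, "out", "z_processed.tsv"),
                     labels = file.path(dir, "labels.tsv"),
                     out_dir = file.path(dir, "out"), penalty = 2, c1 = 2,
                     c2 = 2, n_perm = 49, plots = FALSE)

  spca_fit <- suppressMessages(run_analyze(proc, mode = "spca"))
  scores <- readr::read_tsv(file.path(dir, "out", "spca", "scores.tsv"),
                            show_col_types = FALSE)
  s1 <- dplyr::filter(scores, component == "comp1")
  # a strong planted phenotype factor separates the groups numerically
  expect_lt(separation_statistic(s1$score, s1$label), 0.01)

  scca_fit <- suppressMessages(run_analyze(proc, mode = "scca"))
  meta <- jsonlite::read_json(file.path(dir, "out", "scca", "metadata.json"))
  expect_lte(meta$permutation_p, 0.05)
  expect_true(file.exists(file.path(dir, "out", "scca", "loadings_x.tsv")))

  # the subset search needs n > k + q: point it at a low-dimensional Z slice
  zp <- readr::read_tsv(file.path(dir, "out", "z_processed.tsv"),
                        show_col_types = FALSE)
  readr::write_tsv(zp[, 1:5], file.path(dir, "out", "z_small.tsv"))
  proc_sub <- run_config(x = file.path(dir, "out", "x_processed.tsv"),
                         z = file.path(dir, "out", "z_small.tsv"),
                         labels = file.path(dir, "labels.tsv"),
                         out_dir = file.path(dir, "out"), k = 3, top_m = 10,
                         plots = FALSE)
  sub_fit <- suppressMessages(run_analyze(proc_sub, mode = "subcca"))
  expect_equal(sub_fit$total_evaluated, choose(20, 3))

  de_fit <- suppressMessages(run_analyze(proc, mode = "de"))
  expect_true(file.exists(file.path(dir, "out", "de", "de.tsv")))
})

test_that("independent views leave a near-null sCCA record and empty DE list", {
  dir <- withr::local_tempdir()
  make_pipeline_fixture(dir, effect = 0, seed = 223, shared_factor = FALSE)
  cfg <- run_config(x = file.path(dir, "x.tsv"), z = file.path(dir, "z.tsv"),
                    labels = file.path(dir, "labels.tsv"),
                    out_dir = file.path(dir, "out"), min_prevalence = 0,
                    c1 = 2, c2 = 2, n_perm = 49, seed = 227, plots = FALSE)
  suppressMessages(run_preprocess(cfg))
  proc <- run_config(x = file.path(dir, "out", "x_processed.tsv"),
                     z = file.path(dir, "out", "z_processed.tsv"),
                     labels = file.path(dir, "labels.tsv"),
                     out_dir = file.path(dir, "out"), c1 = 2, c2 = 2,
                     n_perm = 49, seed = 227, plots = FALSE)
  suppressMessages(run_analyze(proc, mode = "scca"))
  meta <- jsonlite::read_json(file.path(dir, "out", "scca", "metadata.json"))
  expect_gt(meta$permutation_p, 0.05)
  de_tab <- suppressMessages(run_analyze(proc, mode = "de"))
  expect_equal(sum(de_tab$q < 0.05), 0L)
})

test_that("the simulation pipeline writes a deterministic summary", {
  dir <- withr::local_tempdir()
  sc <- sim_scenario(n_per_group = 4, p = 10, q = 6, support_x = 3,
                     support_z = 2, effect = 3, noise_sd_x = 0,
                     noise_sd_z = 0)
  out <- suppressMessages(
    run_simulate(list(out_dir = file.path(dir, "sim"), seed = 5),
                 scenarios = list(strong = sc), methods = "scca",
                 replicates = 2))
  expect_true(file.exists(file.path(dir, "sim", "simulate", "summary.txt")))
  txt <- readLines(file.path(dir, "sim", "simulate", "summary.txt"))
  expect_match(txt[2], "grid cells: 1")
  expect_true(all(out$results$support_f1 == 1))
  out2 <- suppressMessages(
    run_simulate(list(out_dir = file.path(dir, "sim2"), seed = 5),
                 scenarios = list(strong = sc), methods = "scca",
                 replicates = 2))
  expect_identical(out$results, out2$results)
})

test_that("a plot side effect renders without touching any result", {
  dir <- withr::local_tempdir()
  make_pipeline_fixture(dir)
  cfg <- run_config(x = file.path(dir, "x.tsv"), z = file.path(dir, "z.tsv"),
                    labels = file.path(dir, "labels.tsv"),
                    out_dir = file.path(dir, "out"), min_prevalence = 0,
                    skip = c("log", "quantile"), penalty = 2,
                    n_perm = 0, plots = TRUE)
  suppressMessages(run_analyze(cfg, mode = "spca"))
  expect_true(file.exists(file.path(dir, "out", "spca", "scores.pdf")))
})
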