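# Plain-text interchange formats. Matrices travel as TSV with samples in
# rows: first column the sample ID, header row of feature IDs. Gene lists are
# one symbol per line ('#' comments allowed); probe maps are two-column TSV;
# scenarios and run configs are YAML.

#' Read a view matrix from TSV
#'
#' Expects samples in rows: first column `sample` (any name accepted, it is
#' renamed), remaining columns numeric features. A labels file (TSV with
#' columns `sample`, `label`) can be joined in the same call.
#'
#' @param path Path to the matrix TSV.
#' @param labels_path Optional path to a sample-label TSV.
#' @return A view tibble.
#' @export
read_view_tsv <- function(path, labels_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  data <- readr::read_tsv(path, show_col_types = FALSE,
                          name_repair = "minimal")
  prob <- readr::problems(data)
  if (nrow(prob) > 0L) {
    stop("malformed TSV '", path, "': ", prob$expected[1L], " expected at ",
         "line ", prob$row[1L] + 1L, call. = FALSE)
  }
  names(data)[1L] <- "sample"
  data$sample <- as.character(data$sample)
  feat <- setdiff(names(data), c("sample", "label"))
  bad <- feat[!vapply(data[feat], is.numeric, logical(1))]
  if (length(bad) > 0L) {
    stop("malformed TSV '", path, "': non-numeric feature column(s) ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  if (!is.null(labels_path)) {
    labels <- read_labels_tsv(labels_path)
    data$label <- NULL
    data <- dplyr::left_join(data, labels, by = "sample")
    if (anyNA(data$label)) {
      stop("labels file '", labels_path, "' is missing some samples",
           call. = FALSE)
    }
    data <- dplyr::relocate(data, "sample", "label")
  }
  data
}

read_labels_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  labels <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("sample", "label") %in% names(labels))) {
    stop("labels file must have columns 'sample' and 'label'", call. = FALSE)
  }
  labels$sample <- as.character(labels$sample)
  labels[c("sample", "label")]
}

#' Write a view matrix to TSV
#'
#' @param data View tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_view_tsv <- function(data, path) {
  readr::write_tsv(data, path)
  invisible(path)
}

#' Read a gene list
#'
#' Plain text, one symbol per line; `#` starts a comment; blank lines and
#' duplicate symbols are dropped.
#'
#' @param path Path to the list file.
#' @return Character vector of symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  symbols <- trimws(lines)
  symbols <- symbols[nzchar(symbols)]
  symbols <- symbols[!duplicated(tolower(symbols))]
  if (length(symbols) == 0L) {
    stop("gene list '", path, "' is empty", call. = FALSE)
  }
  symbols
}

#' Read a probe-to-gene map
#'
#' Two-column TSV with header `probe`, `gene`.
#'
#' @param path Path to the map file.
#' @return Tibble with columns `probe`, `gene`.
#' @export
read_probe_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  map <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("probe", "gene") %in% names(map))) {
    stop("probe map must have columns 'probe' and 'gene'", call. = FALSE)
  }
  map
}

#' Write / read a simulation scenario as YAML
#'
#' @param scenario A `sim_scenario`.
#' @param path File path.
#' @return `write_scenario_yaml` invisibly returns `path`;
#'   `read_scenario_yaml` returns the `sim_scenario`.
#' @export
write_scenario_yaml <- function(scenario, path) {
  stopifnot(inherits(scenario, "sim_scenario"))
  yaml::write_yaml(unclass(scenario), path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  do.call(sim_scenario, yaml::read_yaml(path))
}
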