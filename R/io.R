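## Lossless tab-separated / JSON readers and writers for every interchange
## format. Matrix files follow the small RNA-seq convention: rows = miRNAs
## (or features), columns = samples, first column holds the identifier;
## metadata lives in a companion sample table.

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

#' Read / write a regulation edge table
#'
#' Tab-separated with header `regulator<TAB>target[<TAB>source]`.
#'
#' @param path File path.
#' @return Tibble with columns `regulator`, `target` and (optionally)
#'   `source`.
#' @export
read_regulation <- function(path) {
  x <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  check_regulation(x, path)
  x
}

#' @rdname read_regulation
#' @param x Regulation tibble.
#' @export
write_regulation <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read / write a precursor-to-mature miRNA map
#'
#' Tab-separated `precursor_id<TAB>mature_id`, repeated precursor rows
#' allowed (one mature form per row).
#'
#' @param path File path.
#' @return Tibble with columns `precursor_id`, `mature_id`.
#' @export
read_precursor_map <- function(path) {
  x <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  if (!all(c("precursor_id", "mature_id") %in% names(x))) {
    abort(sprintf("`%s` must have columns precursor_id and mature_id", path))
  }
  x
}

#' @rdname read_precursor_map
#' @param x Precursor map tibble.
#' @export
write_precursor_map <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read / write a miRNA interaction network
#'
#' Tab-separated `source_mirna<TAB>target_mirna<TAB>mediators` with the
#' mediating TF set comma-joined; the round-trip is lossless.
#'
#' @param path File path.
#' @return An `errmir_network`.
#' @export
read_network <- function(path) {
  x <- read_tsv_quiet(path, col_types = readr::cols(.default = "c"))
  if (!all(c("source_mirna", "target_mirna", "mediators") %in% names(x))) {
    abort(sprintf(
      "`%s` must have columns source_mirna, target_mirna, mediators", path))
  }
  x$mediators <- stringr::str_split(x$mediators, stringr::fixed(","))
  new_network(as_tibble(x))
}

#' @rdname read_network
#' @param network An `errmir_network`.
#' @export
write_network <- function(network, path) {
  out <- tibble(
    source_mirna = network$source_mirna,
    target_mirna = network$target_mirna,
    mediators = purrr::map_chr(network$mediators, paste, collapse = ","))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read / write a wide sample table (expression or feature matrix)
#'
#' The matrix file stores variables in rows and samples in columns with an
#' identifier first column (`mirna_id` or `feature_id`); the metadata file
#' is tab-separated `sample_id<TAB>label<TAB>batch` with `label` in {0, 1}
#' (1 = disease). The reader returns the package's wide samples x
#' variables tibble.
#'
#' @param path Matrix file path.
#' @param meta_path Metadata file path.
#' @param unit `"rpm"` (default) or `"counts"`, recorded as an attribute.
#' @return Wide tibble with metadata columns plus one column per variable.
#' @export
read_sample_table <- function(path, meta_path, unit = "rpm") {
  mat <- read_tsv_quiet(path)
  if (nrow(mat) == 0) abort(sprintf("`%s` contains no rows", path))
  id_col <- names(mat)[1]
  meta <- read_tsv_quiet(
    meta_path,
    col_types = readr::cols(sample_id = "c", label = "i", batch = "c"))
  missing <- setdiff(META_COLS, names(meta))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing metadata column(s): %s", meta_path,
                  paste(missing, collapse = ", ")))
  }
  samples <- setdiff(names(mat), id_col)
  uncovered <- setdiff(samples, meta$sample_id)
  if (length(uncovered) > 0) {
    abort(sprintf("metadata does not cover sample(s): %s",
                  paste(uncovered, collapse = ", ")))
  }
  vals <- t(as.matrix(mat[, samples, drop = FALSE]))
  colnames(vals) <- mat[[id_col]]
  meta <- meta[match(samples, meta$sample_id), META_COLS]
  out <- dplyr::bind_cols(as_tibble(meta), as_tibble(vals))
  expr_unit(out) <- unit
  check_sample_table(out)
  out
}

#' @rdname read_sample_table
#' @param data Wide sample tibble.
#' @param id_col Name of the identifier column written to the matrix file
#'   (`"mirna_id"` for expression, `"feature_id"` for features).
#' @export
write_sample_table <- function(data, path, meta_path, id_col = "mirna_id") {
  check_sample_table(data)
  m <- t(measure_matrix(data))
  out <- dplyr::bind_cols(tibble(!!id_col := rownames(m)), as_tibble(m))
  readr::write_tsv(out, path)
  readr::write_tsv(data[META_COLS], meta_path)
  invisible(path)
}

#' Serialize / restore a fitted model as JSON
#'
#' The JSON document carries the marker ids, transform parameters, kernel
#' parameters, support vectors and coefficients, Platt calibration
#' coefficients and the frozen operating threshold — everything
#' [risk_score()] needs, with no binary payload.
#'
#' @param model An `errmir_model`.
#' @param path Output path.
#' @export
write_model <- function(model, path) {
  payload <- unclass(model)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  # jsonlite serializes matrices row-major as nested arrays; a single
  # support vector comes back as a plain vector
  payload$sv <- matrix(as.numeric(payload$sv),
                       ncol = length(payload$markers))
  payload$coefs <- as.numeric(payload$coefs)
  payload$center <- setNames(as.numeric(payload$center), payload$markers)
  payload$scale <- setNames(as.numeric(payload$scale), payload$markers)
  structure(payload, class = "errmir_model")
}

#' Write an evaluation report as JSON (with embedded ROC points)
#'
#' @param eval An `errmir_eval`.
#' @param path Output path.
#' @export
write_eval <- function(eval, path) {
  payload <- list(
    sensitivity = eval$sensitivity, specificity = eval$specificity,
    auc = eval$auc, threshold = eval$threshold,
    threshold_policy = eval$threshold_policy,
    n_control = eval$n_control, n_disease = eval$n_disease,
    roc = eval$roc)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' Read a run-configuration YAML document
#'
#' Recognized keys: `seed`, `filter_threshold`, `filter_agg`, `alpha`,
#' `fc_min`, `test`, `train_fraction`, `k_markers`, `cost`,
#' `threshold_policy`, `log_offset`, and a `ga` block accepting
#' [ga_config()] arguments. Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return Named list of configuration values merged over the defaults.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path) %||% list()
  defaults <- default_run_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  ga_args <- raw$ga %||% list()
  unknown_ga <- setdiff(names(ga_args), names(formals(ga_config)))
  if (length(unknown_ga) > 0) {
    abort(sprintf("unknown ga configuration key(s): %s",
                  paste(unknown_ga, collapse = ", ")))
  }
  cfg <- modifyList(defaults, raw[setdiff(names(raw), "ga")])
  cfg$ga <- ga_args
  cfg
}

default_run_config <- function() {
  list(seed = 1, filter_threshold = 100, filter_agg = "median",
       alpha = 0.05, fc_min = 0.5, test = "wilcox",
       train_fraction = 0.75, k_markers = 3, cost = 1,
       threshold_policy = "youden_train", log_offset = 2^-20,
       ga = list())
}
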