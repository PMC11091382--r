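#' End-to-end marker discovery on one dataset
#'
#' Executes the full discovery pipeline on a labelled RPM expression table:
#' stratified train/test split, abundance filtering on the training
#' samples only (the retained set is frozen), ratio-feature generation for
#' network-connected pairs, univariate candidate screening on the training
#' features, repeated genetic-algorithm subset selection with frequency
#' tallying, top-k marker extraction, SVM training, and evaluation on the
#' held-out test samples at the training-frozen Youden threshold.
#'
#' @param expression Wide RPM expression tibble (metadata columns
#'   `sample_id`, `label`, `batch`).
#' @param network An `errmir_network` (mature-level ids matching the
#'   expression columns).
#' @param config Named list as produced by [read_run_config()] /
#'   `default_run_config()`; individual entries may be overridden via
#'   `...`.
#' @param ... Configuration overrides (e.g. `seed = 7`,
#'   `ga = list(n_repeats = 20)`).
#' @param use_univariate When `FALSE`, the univariate candidate filter is
#'   bypassed and all features enter the GA.
#' @return A list of class `errmir_discovery`: `univariate`, `frequency`,
#'   `markers`, `model`, `eval_test`, `retained`, `split`, and a
#'   `manifest` recording the configuration and seed.
#' @export
run_discover <- function(expression, network, config = NULL, ...,
                         use_univariate = TRUE) {
  cfg <- modifyList(config %||% default_run_config(), list(...))
  check_sample_table(expression, "expression")

  split <- split_train_test(expression, cfg$train_fraction, seed = cfg$seed)
  retained <- filter_low_expression(split$train, cfg$filter_threshold,
                                    cfg$filter_agg)
  feats_train <- compute_errmir(split$train, network, retained)
  feats_test <- compute_errmir(split$test, network, retained)

  univ <- univariate_screen(feats_train, alpha = cfg$alpha,
                            fc_min = cfg$fc_min, test = cfg$test,
                            log_offset = cfg$log_offset)
  candidates <- if (use_univariate) {
    univ$feature_id[univ$candidate]
  } else {
    measure_cols(feats_train)
  }
  if (length(candidates) < 2) {
    abort(sprintf(
      "only %d candidate feature(s) pass the univariate filter; relax alpha/fc_min or set use_univariate = FALSE",
      length(candidates)))
  }

  ga_cfg <- do.call(ga_config, modifyList(
    list(seed = cfg$seed, cost = cfg$cost, log_offset = cfg$log_offset),
    cfg$ga %||% list()))
  freq <- repeat_ga(feats_train, ga_cfg, features = radix_sort(candidates))
  markers <- top_k_markers(freq, cfg$k_markers)

  model <- train_model(feats_train, markers, cost = cfg$cost,
                       log_offset = cfg$log_offset,
                       probability_seed = cfg$seed)
  eval_test <- evaluate(model, feats_test,
                        threshold_policy = cfg$threshold_policy)
  out <- list(
    univariate = univ, frequency = freq, markers = markers,
    model = model, eval_test = eval_test, retained = retained,
    split = split,
    manifest = list(config = cfg, seed = cfg$seed,
                    n_samples = nrow(expression),
                    n_mirnas = length(measure_cols(expression)),
                    n_edges = nrow(network),
                    n_candidates = length(candidates)))
  class(out) <- "errmir_discovery"
  out
}

#' @export
print.errmir_discovery <- function(x, ...) {
  cat(sprintf(
    "# ERRmiR discovery: %d retained miRNAs, %d candidates, markers: %s\n",
    length(x$retained), x$manifest$n_candidates,
    paste(x$markers, collapse = ", ")))
  print(x$eval_test)
  invisible(x)
}

#' Validate a fitted marker model on an external dataset
#'
#' Recomputes the marker ratio features directly on the validation
#' expression table (the marker panel is fixed, so no abundance
#' re-filtering is applied — mirroring clinical deployment of a fixed
#' panel), scores the samples and evaluates at the model's frozen
#' threshold.
#'
#' @param model An `errmir_model` whose markers are `"a|b"` ratio ids.
#' @param expression Wide RPM expression tibble of the validation cohort.
#' @param network Optional `errmir_network` used to annotate the marker
#'   edges; validation only needs the marker miRNAs themselves.
#' @param threshold_policy Passed to [evaluate()].
#' @return An `errmir_eval`.
#' @export
run_validate <- function(model, expression, network = NULL,
                         threshold_policy = "youden_train") {
  check_sample_table(expression, "expression")
  parts <- stringr::str_split_fixed(model$markers, stringr::fixed("|"), 2)
  needed <- unique(as.vector(parts))
  missing <- setdiff(needed, names(expression))
  if (length(missing) > 0) {
    abort(sprintf("marker miRNA(s) absent from validation data: %s",
                  paste(missing, collapse = ", ")))
  }
  m <- measure_matrix(expression, needed)
  vals <- m[, parts[, 1], drop = FALSE] / (m[, parts[, 2], drop = FALSE] + 1)
  colnames(vals) <- model$markers
  feats <- dplyr::bind_cols(expression[META_COLS], as_tibble(vals))
  evaluate(model, feats, threshold_policy = threshold_policy)
}
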