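#' Tidy and glance methods for fitted ERRmiR objects
#'
#' `tidy()` returns per-component tables (markers with their transform
#' parameters for a model, ROC points for an evaluation, per-feature
#' counts for a frequency table); `glance()` returns one-row model- or
#' report-level summaries.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @name errmir_tidiers
NULL

#' @rdname errmir_tidiers
#' @export
tidy.errmir_model <- function(x, ...) {
  tibble(marker = x$markers,
         center = unname(x$center),
         scale = unname(x$scale))
}

#' @rdname errmir_tidiers
#' @export
glance.errmir_model <- function(x, ...) {
  tibble(n_markers = length(x$markers), n_train = x$n_train,
         n_support_vectors = nrow(x$sv), cost = x$cost, gamma = x$gamma,
         threshold = x$threshold, train_auc = x$train_auc)
}

#' @rdname errmir_tidiers
#' @export
tidy.errmir_eval <- function(x, ...) x$roc

#' @rdname errmir_tidiers
#' @export
glance.errmir_eval <- function(x, ...) {
  tibble(sensitivity = x$sensitivity, specificity = x$specificity,
         auc = x$auc, threshold = x$threshold,
         n_control = x$n_control, n_disease = x$n_disease)
}

#' @rdname errmir_tidiers
#' @export
tidy.errmir_freq <- function(x, ...) {
  as_tibble(x)
}

#' @rdname errmir_tidiers
#' @export
glance.errmir_freq <- function(x, ...) {
  tibble(n_features = nrow(x), n_repeats = attr(x, "n_repeats"),
         n_selected = sum(x$count > 0), max_count = max(x$count))
}

#' @rdname errmir_tidiers
#' @export
glance.errmir_discovery <- function(x, ...) {
  dplyr::bind_cols(
    tibble(n_retained = length(x$retained),
           n_candidates = x$manifest$n_candidates,
           markers = paste(x$markers, collapse = ",")),
    glance(x$eval_test))
}
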