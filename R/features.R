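#' Convert raw counts to reads per million (RPM)
#'
#' @param data Wide expression tibble (metadata columns plus one numeric
#'   column per miRNA) holding raw counts.
#' @param totals Optional named numeric vector of per-sample mapped-read
#'   totals (names = sample ids). When `NULL`, each sample's total is the
#'   sum of its miRNA columns, so every row of the result sums to 1e6.
#' @return The same tibble with values scaled to RPM (`unit` attribute set
#'   to `"rpm"`).
#' @export
counts_to_rpm <- function(data, totals = NULL) {
  check_sample_table(data)
  check_nonnegative(data)
  cols <- measure_cols(data)
  m <- measure_matrix(data, cols)
  if (is.null(totals)) {
    tot <- rowSums(m)
  } else {
    missing <- setdiff(data$sample_id, names(totals))
    if (length(missing) > 0) {
      abort(sprintf("`totals` missing sample(s): %s",
                    paste(missing, collapse = ", ")))
    }
    tot <- as.numeric(totals[data$sample_id])
  }
  bad <- data$sample_id[!is.finite(tot) | tot <= 0]
  if (length(bad) > 0) {
    abort(sprintf("zero or invalid read total for sample(s): %s",
                  paste(bad, collapse = ", ")))
  }
  data[cols] <- as_tibble(m * (1e6 / tot))
  expr_unit(data) <- "rpm"
  data
}

#' Retain miRNAs with stable detection above an abundance threshold
#'
#' A miRNA is retained when its aggregated RPM across the supplied
#' (training) samples reaches `threshold`. The aggregation defaults to the
#' median; low-abundance miRNAs below the cutoff give unstable ratios and
#' are excluded before feature generation.
#'
#' @param data Wide RPM expression tibble.
#' @param threshold Minimum aggregated RPM (default 100).
#' @param agg Aggregation rule: `"median"` (default), `"mean"` or `"min"`.
#' @return Character vector of retained miRNA ids (lexicographic order).
#' @export
filter_low_expression <- function(data, threshold = 100,
                                  agg = c("median", "mean", "min")) {
  agg <- match.arg(agg)
  check_sample_table(data)
  m <- measure_matrix(data)
  stat <- switch(agg,
    median = apply(m, 2, median),
    mean   = colMeans(m),
    min    = apply(m, 2, min))
  retained <- radix_sort(colnames(m)[stat >= threshold])
  if (length(retained) == 0) {
    abort(sprintf(
      "no miRNA passes the %s-RPM %s filter; consider a lower threshold",
      format(threshold), agg))
  }
  retained
}

#' Compute ERRmiR ratio features for network-connected miRNA pairs
#'
#' For every directed network edge (a, b) with both endpoints in `retained`,
#' the feature value per sample is `expr(a) / (expr(b) + 1)`; the +1 offset
#' in the denominator guards against division by zero. Feature columns are
#' named `"a|b"` and ordered lexicographically by (a, b).
#'
#' @param data Wide RPM expression tibble.
#' @param network An `errmir_network`.
#' @param retained Character vector of retained miRNA ids; defaults to all
#'   miRNAs present in `data`.
#' @return A wide feature tibble (metadata columns plus one column per
#'   ratio feature) with a `features` attribute: a tibble of `feature_id`,
#'   `numerator`, `denominator` and the edge's `mediators`.
#' @export
compute_errmir <- function(data, network, retained = NULL) {
  check_sample_table(data)
  check_nonnegative(data)
  mirnas <- measure_cols(data)
  retained <- if (is.null(retained)) mirnas else intersect(retained, mirnas)
  edges <- connected_pairs(network, retained)
  if (nrow(edges) == 0) {
    abort("no network edge has both endpoints among the retained miRNAs")
  }
  m <- measure_matrix(data)
  vals <- m[, edges$source_mirna, drop = FALSE] /
    (m[, edges$target_mirna, drop = FALSE] + 1)
  feats <- tibble(
    feature_id = paste(edges$source_mirna, edges$target_mirna, sep = "|"),
    numerator = edges$source_mirna,
    denominator = edges$target_mirna,
    mediators = edges$mediators)
  colnames(vals) <- feats$feature_id
  out <- dplyr::bind_cols(data[META_COLS], as_tibble(vals))
  attr(out, "features") <- feats
  out
}

#' Feature annotation of an ERRmiR feature table
#'
#' @param features A feature tibble produced by [compute_errmir()].
#' @return Tibble of `feature_id`, `numerator`, `denominator`, `mediators`;
#'   reconstructed from the `"a|b"` column names if the attribute is absent
#'   (e.g. after a round-trip through disk).
#' @export
feature_info <- function(features) {
  info <- attr(features, "features")
  if (!is.null(info)) return(info)
  ids <- measure_cols(features)
  parts <- stringr::str_split_fixed(ids, stringr::fixed("|"), 2)
  tibble(feature_id = ids, numerator = parts[, 1], denominator = parts[, 2],
         mediators = rep(list(character(0)), length(ids)))
}

## log2 transform used for ratio features downstream; the small offset
## keeps zero ratios finite without distorting values of magnitude >= 1.
log2_offset <- function(x, offset = 2^-20) log2(x + offset)
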