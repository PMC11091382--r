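#' Cross-batch stability of raw expression versus ERRmiR ratio features
#'
#' Quantifies how much each quantity moves between batches: for every miRNA
#' the per-batch median of log2(RPM + 1), and for every ERRmiR feature the
#' per-batch median of log2(ratio + offset), are compared across batches;
#' the reported `shift` is the range (max minus min) of the per-batch
#' medians, i.e. the absolute difference for two batches. Per-sample
#' quartile summaries of both distributions are returned for quartile-plot
#' style diagnostics. Library-size batch factors shift raw log2 expression
#' by the full log2 factor but nearly cancel in the ratios, which is the
#' mechanism that makes ratio features batch-insensitive.
#'
#' @param data Wide RPM expression tibble covering at least two batches
#'   (`batch` metadata column).
#' @param network An `errmir_network`.
#' @param threshold Abundance filter applied to the pooled data before
#'   forming ratio features (default 100 RPM).
#' @param agg Aggregation rule for the filter.
#' @param offset Offset inside the feature log2 transform (default 2^-20).
#' @return An object of class `errmir_stability`: a list with tibbles
#'   `shifts` (`type` = raw/errmir, `id`, `shift`, plus the per-batch
#'   medians in a list-column), `sample_quartiles` (`sample_id`, `batch`,
#'   `type`, `q25`, `median`, `q75`) and a `summary` of shift quantiles
#'   per type.
#' @export
batch_stability_report <- function(data, network, threshold = 100,
                                   agg = "median", offset = 2^-20) {
  check_sample_table(data)
  batches <- unique(data$batch)
  if (length(batches) < 2) abort("stability report needs >= 2 batches")
  small <- table(data$batch)
  if (any(small < 3)) {
    warn(sprintf("batch(es) with < 3 samples: %s",
                 paste(names(small)[small < 3], collapse = ", ")))
  }
  retained <- filter_low_expression(data, threshold = threshold, agg = agg)
  feats <- compute_errmir(data, network, retained)

  raw_log <- data
  raw_log[measure_cols(data)] <-
    as_tibble(log2(measure_matrix(data) + 1))
  feat_log <- feats
  feat_log[measure_cols(feats)] <-
    as_tibble(log2_offset(measure_matrix(feats), offset))

  shift_tbl <- function(tbl, type) {
    long <- tidyr::pivot_longer(tbl, cols = all_of(measure_cols(tbl)),
                                names_to = "id", values_to = "value")
    long |>
      group_by(.data$id, .data$batch) |>
      summarise(med = median(.data$value), .groups = "drop") |>
      group_by(.data$id) |>
      summarise(shift = max(.data$med) - min(.data$med),
                batch_medians = list(setNames(.data$med, .data$batch)),
                .groups = "drop") |>
      mutate(type = type, .before = 1)
  }
  quart_tbl <- function(tbl, type) {
    m <- measure_matrix(tbl)
    tibble(sample_id = tbl$sample_id, batch = tbl$batch, type = type,
           q25 = apply(m, 1, quantile, 0.25),
           median = apply(m, 1, median),
           q75 = apply(m, 1, quantile, 0.75))
  }

  shifts <- bind_rows(shift_tbl(raw_log, "raw"), shift_tbl(feat_log, "errmir"))
  summary <- shifts |>
    group_by(.data$type) |>
    summarise(
      q25 = quantile(.data$shift, 0.25), median = median(.data$shift),
      q75 = quantile(.data$shift, 0.75), max = max(.data$shift),
      .groups = "drop")
  out <- list(
    shifts = shifts,
    sample_quartiles = bind_rows(quart_tbl(raw_log, "raw"),
                                 quart_tbl(feat_log, "errmir")),
    summary = summary,
    retained = retained)
  class(out) <- "errmir_stability"
  out
}

#' @export
print.errmir_stability <- function(x, ...) {
  cat("# Cross-batch stability report (log2 median shifts)\n")
  print(x$summary)
  invisible(x)
}

#' @rdname batch_stability_report
#' @param x An `errmir_stability` object.
#' @param ... Unused.
#' @export
tidy.errmir_stability <- function(x, ...) x$shifts
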