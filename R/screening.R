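#' Univariate differential screening of features
#'
#' Per feature: the log2 fold change (mean log2 value in disease minus
#' control), a two-group p-value (two-sided Mann-Whitney U by default, the
#' distribution-free choice for right-skewed ratios; Welch's t available)
#' and the Benjamini-Hochberg adjusted q-value over all tested features.
#' Candidate features satisfy `q_value < alpha` and `|log2_fc| >= fc_min`.
#'
#' @param data Wide feature (or expression) tibble with `label` metadata.
#' @param alpha FDR level for the candidate filter (default 0.05).
#' @param fc_min Minimum absolute log2 fold change for candidates
#'   (default 0.5, about a 1.4-fold ratio shift).
#' @param test `"wilcox"` (default) or `"welch"`.
#' @param log_offset Offset inside the log2 transform; 2^-20 for ratio
#'   features, use 1 for raw expression values.
#' @return Tibble of `feature_id`, `log2_fc`, `p_value`, `q_value`,
#'   `candidate` (logical), sorted by p-value. Constant features get
#'   p = 1 by convention.
#' @export
univariate_screen <- function(data, alpha = 0.05, fc_min = 0.5,
                              test = c("wilcox", "welch"),
                              log_offset = 2^-20) {
  test <- match.arg(test)
  check_sample_table(data)
  y <- data$label
  if (sum(y == 1) < 3 || sum(y == 0) < 3) {
    abort("both groups need >= 3 samples for univariate screening")
  }
  m <- log2_offset(measure_matrix(data), log_offset)
  res <- purrr::map(colnames(m), function(id) {
    v <- m[, id]
    lfc <- mean(v[y == 1]) - mean(v[y == 0])
    p <- if (length(unique(v)) == 1) {
      1
    } else if (test == "wilcox") {
      suppressWarnings(wilcox.test(v[y == 1], v[y == 0])$p.value)
    } else {
      t.test(v[y == 1], v[y == 0])$p.value
    }
    tibble(feature_id = id, log2_fc = lfc, p_value = p)
  })
  out <- bind_rows(res)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$candidate <- out$q_value < alpha & abs(out$log2_fc) >= fc_min
  n_const <- sum(out$p_value == 1 &
                   apply(m, 2, function(v) length(unique(v)) == 1))
  if (n_const > 0) {
    inform(sprintf("univariate_screen: %d constant feature(s) assigned p = 1",
                   n_const))
  }
  dplyr::arrange(out, .data$p_value, .data$feature_id)
}
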