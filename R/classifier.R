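#' Stratified train/test split
#'
#' Allocates `round(train_fraction * n)` samples to the training set,
#' distributed across the two classes by largest-remainder apportionment of
#' each class's exact quota (so a 50/50 cohort of 100 splits 75/25 with
#' class proportions preserved to rounding). Reproducible by seed.
#'
#' @param data Wide sample table with `label` metadata.
#' @param train_fraction Fraction of samples in the training set
#'   (default 0.75).
#' @param seed Seed for the within-class shuffles.
#' @return List with tibbles `train` and `test` (disjoint, exhaustive).
#' @export
split_train_test <- function(data, train_fraction = 0.75, seed = 1) {
  check_sample_table(data)
  stopifnot(train_fraction > 0, train_fraction < 1)
  counts <- table(factor(data$label, levels = c(0, 1)))
  if (any(counts < 2)) abort("each class needs >= 2 samples to split")
  n_train <- round(train_fraction * nrow(data))
  quota <- train_fraction * as.numeric(counts)
  take <- floor(quota)
  remainder <- n_train - sum(take)
  if (remainder > 0) {
    # hand leftover slots to the classes with the largest fractional parts
    # (ties resolved toward the earlier class level)
    ord <- order(-(quota - take), seq_along(quota))
    take[ord[seq_len(remainder)]] <- take[ord[seq_len(remainder)]] + 1
  }
  train_idx <- withr::with_seed(seed, {
    unlist(purrr::map2(c(0, 1), take, function(cls, k) {
      idx <- which(data$label == cls)
      sample(idx)[seq_len(k)]
    }))
  })
  list(train = data[sort(train_idx), , drop = FALSE],
       test = data[setdiff(seq_len(nrow(data)), train_idx), , drop = FALSE])
}

#' Train the marker-panel support-vector classifier
#'
#' Fits the diagnostic pipeline on the training samples: log2 transform of
#' each marker feature, per-feature standardization with training
#' statistics, then a radial-kernel C-support vector classifier with
#' probability calibration (Platt scaling via libsvm's internal
#' cross-validation). The kernel width follows the "scale" convention,
#' gamma = 1 / (d * mean feature variance) on the transformed training
#' data (approximately 1/d after standardization). The operating threshold
#' on the risk score is chosen by maximizing Youden's J on the training
#' scores and frozen for all later evaluations.
#'
#' @param data Wide feature tibble (training samples).
#' @param markers Marker feature ids (default: all measurement columns).
#' @param cost SVM regularization parameter C (default 1).
#' @param log_offset Offset inside the log2 transform; 2^-20 for ratio
#'   features, 1 for raw expression.
#' @param probability_seed Seed fixed around libsvm's internal
#'   cross-validated Platt calibration, for reproducibility.
#' @return An object of class `errmir_model`.
#' @export
train_model <- function(data, markers = measure_cols(data), cost = 1,
                        log_offset = 2^-20, probability_seed = 1) {
  check_sample_table(data)
  missing <- setdiff(markers, names(data))
  if (length(missing) > 0) {
    abort(sprintf("marker feature(s) absent from data: %s",
                  paste(missing, collapse = ", ")))
  }
  y <- data$label
  if (length(unique(y)) < 2) abort("training data must contain both classes")
  xl <- log2_offset(measure_matrix(data, markers), log_offset)
  center <- colMeans(xl)
  scale <- apply(xl, 2, sd)
  constant <- scale == 0
  if (any(constant)) {
    warn(sprintf("dropping constant marker(s) after transform: %s",
                 paste(markers[constant], collapse = ", ")))
    markers <- markers[!constant]
    if (length(markers) == 0) abort("all markers are constant after transform")
    xl <- xl[, !constant, drop = FALSE]
    center <- center[!constant]
    scale <- scale[!constant]
  }
  xs <- sweep(sweep(xl, 2, center), 2, scale, "/")
  gamma <- 1 / (ncol(xs) * mean(apply(xs, 2, var)))
  yf <- factor(ifelse(y == 1, "disease", "control"),
               levels = c("control", "disease"))
  fit <- withr::with_seed(probability_seed,
    e1071::svm(xs, yf, kernel = "radial", cost = cost, gamma = gamma,
               scale = FALSE, probability = TRUE))
  # libsvm signs decision values toward its first internal label; record
  # the orientation so the serialized model reproduces predict() exactly
  pred <- predict(fit, xs, decision.values = TRUE)
  disease_first <- startsWith(colnames(attr(pred, "decision.values"))[1],
                              "disease")
  model <- structure(list(
    markers = colnames(xs),
    log_offset = log_offset,
    center = center, scale = scale,
    gamma = gamma, cost = cost,
    sv = unname(as.matrix(fit$SV)),
    coefs = drop(fit$coefs),
    rho = fit$rho,
    probA = fit$probA, probB = fit$probB,
    disease_first = disease_first,
    threshold = NA_real_,
    n_train = nrow(xs)), class = "errmir_model")
  scores <- risk_score(model, data)
  model$threshold <- youden_threshold(y, scores)
  model$train_auc <- roc_auc(y, scores)
  model
}

#' Disease risk score of samples under a fitted model
#'
#' Applies the stored transform and the serialized SVM decision function
#' (radial kernel over the support vectors) followed by the fitted Platt
#' sigmoid, yielding the calibrated probability of the disease class.
#'
#' @param model An `errmir_model`.
#' @param data Wide feature tibble containing every marker column.
#' @return Numeric vector of scores in \[0, 1\], one per sample, monotone
#'   in the classifier's decision value.
#' @export
risk_score <- function(model, data) {
  missing <- setdiff(model$markers, names(data))
  if (length(missing) > 0) {
    abort(sprintf("marker feature(s) missing from data: %s",
                  paste(missing, collapse = ", ")))
  }
  xl <- log2_offset(measure_matrix(data, model$markers), model$log_offset)
  xs <- sweep(sweep(xl, 2, model$center), 2, model$scale, "/")
  f <- svm_decision(model, xs)
  p_first <- 1 / (1 + exp(model$probA * f + model$probB))
  if (model$disease_first) p_first else 1 - p_first
}

svm_decision <- function(model, xs) {
  # f(x) = sum_i coef_i exp(-gamma ||sv_i - x||^2) - rho
  cross <- tcrossprod(model$sv, xs)
  d2 <- outer(rowSums(model$sv^2), rowSums(xs^2), "+") - 2 * cross
  drop(crossprod(exp(-model$gamma * pmax(d2, 0)), model$coefs)) - model$rho
}

#' ROC curve over all score thresholds
#'
#' Scores are swept from high to low; tied scores are grouped so the curve
#' follows the midrank tie convention, making the trapezoidal area equal
#' the Mann-Whitney concordance probability.
#'
#' @param labels 0/1 labels.
#' @param scores Numeric scores (higher = more disease-like).
#' @return Tibble of `threshold`, `fpr`, `tpr`, starting at (0, 0) and
#'   ending at (1, 1), both coordinates non-decreasing.
#' @export
roc_curve <- function(labels, scores) {
  if (length(unique(labels)) < 2) {
    abort("ROC undefined: data contains a single class")
  }
  ord <- order(-scores)
  s <- scores[ord]
  y <- labels[ord]
  last <- !duplicated(s, fromLast = TRUE)  # group ties
  tp <- cumsum(y == 1)[last]
  fp <- cumsum(y == 0)[last]
  tibble(threshold = c(Inf, s[last]),
         fpr = c(0, fp / sum(labels == 0)),
         tpr = c(0, tp / sum(labels == 1)))
}

#' Trapezoidal area under the ROC curve
#'
#' @inheritParams roc_curve
#' @return AUC in \[0, 1\]; with the midrank tie convention this equals the
#'   probability that a random disease sample outscores a random control
#'   (ties counting one half).
#' @export
roc_auc <- function(labels, scores) {
  if (length(unique(labels)) < 2) {
    abort("AUC undefined: data contains a single class")
  }
  ord <- order(-scores)
  s <- scores[ord]
  y <- labels[ord]
  last <- !duplicated(s, fromLast = TRUE)
  tp <- c(0, cumsum(y == 1)[last])
  fp <- c(0, cumsum(y == 0)[last])
  # trapezoid area accumulated in integer counts (one final division), so
  # the result is bit-identical to the Mann-Whitney concordance mean
  n0 <- sum(labels == 0)
  n1 <- sum(labels == 1)
  sum(diff(fp) * (head(tp, -1) + tp[-1])) / (2 * n0 * n1)
}

youden_threshold <- function(labels, scores) {
  cand <- sort(unique(scores))
  j <- purrr::map_dbl(cand, function(t) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    sens + spec - 1
  })
  # among ties keep the highest threshold (most specific operating point)
  max(cand[j == max(j)])
}

#' Evaluate a fitted model on labelled samples
#'
#' Computes the full ROC curve and trapezoidal AUC of the risk scores, and
#' sensitivity/specificity at the operating threshold: by default the
#' Youden-optimal threshold frozen from the training data
#' (`threshold_policy = "youden_train"`), alternatively a fixed 0.5 cut
#' (`"fixed"`). A sample is called disease when its score >= threshold.
#'
#' @param model An `errmir_model`.
#' @param data Wide feature tibble with `label` metadata and all marker
#'   columns; must contain both classes.
#' @param threshold_policy `"youden_train"` (default) or `"fixed"`.
#' @param fixed_threshold Cutoff used under the `"fixed"` policy.
#' @return An object of class `errmir_eval`: list with `sensitivity`,
#'   `specificity`, `auc`, `threshold`, `roc` (tibble of points),
#'   `scores`, `n_control`, `n_disease`.
#' @export
evaluate <- function(model, data,
                     threshold_policy = c("youden_train", "fixed"),
                     fixed_threshold = 0.5) {
  threshold_policy <- match.arg(threshold_policy)
  check_sample_table(data)
  y <- data$label
  if (length(unique(y)) < 2) {
    abort("evaluation data contains a single class; AUC undefined")
  }
  scores <- risk_score(model, data)
  thr <- if (threshold_policy == "youden_train") model$threshold
         else fixed_threshold
  out <- list(
    sensitivity = mean(scores[y == 1] >= thr),
    specificity = mean(scores[y == 0] < thr),
    auc = roc_auc(y, scores),
    threshold = thr,
    threshold_policy = threshold_policy,
    roc = roc_curve(y, scores),
    scores = tibble(sample_id = data$sample_id, label = y, score = scores),
    n_control = sum(y == 0),
    n_disease = sum(y == 1))
  class(out) <- "errmir_eval"
  out
}

#' @export
print.errmir_eval <- function(x, ...) {
  cat(sprintf(
    "# ERRmiR evaluation: AUC %.3f | sensitivity %.3f | specificity %.3f (threshold %.3f, %d control / %d disease)\n",
    x$auc, x$sensitivity, x$specificity, x$threshold,
    x$n_control, x$n_disease))
  invisible(x)
}

#' Learning curve of the marker classifier
#'
#' For each training-set size, a stratified subsample is drawn and scored
#' by stratified cross-validation: the model is fitted on the training
#' folds and AUC is recorded on both the training folds (train score) and
#' the held-out fold (cross-validation score). A persistent gap between
#' the two curves that does not close with more data indicates
#' overfitting.
#'
#' @param data Wide feature tibble (training samples).
#' @param markers Marker feature ids.
#' @param sizes Increasing vector of training-set sizes to probe.
#' @param cv_folds Folds per size (default 5).
#' @param seed Seed for subsampling and fold assignment.
#' @param ... Passed to [train_model()].
#' @return Tibble of class `errmir_learning_curve` with `size`,
#'   `train_score`, `cv_score`. Sizes too small to hold both classes in
#'   every fold are skipped with a warning.
#' @export
learning_curve <- function(data, markers = measure_cols(data),
                           sizes = NULL, cv_folds = 5, seed = 1, ...) {
  check_sample_table(data)
  n <- nrow(data)
  sizes <- sizes %||% unique(round(seq(0.2, 1, length.out = 5) * n))
  sizes <- sort(sizes[sizes <= n])
  rows <- purrr::map(sizes, function(sz) {
    sub <- withr::with_seed(seed + sz, {
      idx <- unlist(purrr::map(c(0, 1), function(cls) {
        cls_idx <- which(data$label == cls)
        k <- max(1, round(sz * length(cls_idx) / n))
        sample(cls_idx)[seq_len(min(k, length(cls_idx)))]
      }))
      data[sort(idx), , drop = FALSE]
    })
    if (min(table(sub$label)) < cv_folds) {
      warn(sprintf("size %d: fewer samples than folds in a class; skipped", sz))
      return(NULL)
    }
    folds <- make_cv_folds(sub$label, cv_folds, seed)
    fold_scores <- purrr::map(sort(unique(folds)), function(f) {
      tr <- sub[folds != f, , drop = FALSE]
      te <- sub[folds == f, , drop = FALSE]
      if (length(unique(te$label)) < 2) return(NULL)
      m <- suppressWarnings(train_model(tr, markers, ...))
      c(train = roc_auc(tr$label, risk_score(m, tr)),
        cv = roc_auc(te$label, risk_score(m, te)))
    })
    fold_scores <- do.call(rbind, fold_scores)
    tibble(size = nrow(sub),
           train_score = mean(fold_scores[, "train"]),
           cv_score = mean(fold_scores[, "cv"]))
  })
  out <- bind_rows(rows)
  class(out) <- c("errmir_learning_curve", class(out))
  out
}
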