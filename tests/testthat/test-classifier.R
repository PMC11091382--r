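make_sep_data <- function(n_per_group = 20, gap = 4, noise = 0.3,
                          seed = 1, n_extra = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_group
    label <- rep(c(0L, 1L), each = n_per_group)
    m <- cbind(f1 = 2^(6 + label * gap + rnorm(n, 0, noise)),
               sapply(seq_len(n_extra), function(i) 2^rnorm(n, 8, 1)))
    colnames(m) <- c("f1", sprintf("x%d", seq_len(n_extra)))
    sample_table(m, label = label)
  })
}

test_that("stratified split honors the 0.75 contract and is seed-reproducible", {
  data <- make_sep_data(50)  # 100 samples, 50/50
  sp <- split_train_test(data, 0.75, seed = 3)
  expect_equal(nrow(sp$train), 75)
  expect_equal(nrow(sp$test), 25)
  expect_setequal(as.integer(table(sp$train$label)), c(38L, 37L))
  expect_setequal(c(sp$train$sample_id, sp$test$sample_id), data$sample_id)
  expect_length(intersect(sp$train$sample_id, sp$test$sample_id), 0)

  sp2 <- split_train_test(data, 0.75, seed = 3)
  expect_identical(sp$train$sample_id, sp2$train$sample_id)
  sp3 <- split_train_test(data, 0.75, seed = 4)
  expect_false(identical(sp$train$sample_id, sp3$train$sample_id))

  # 7/5 class sizes: 12 samples -> 9 train, apportioned 5/4
  small <- make_sep_data(6)[c(1:7, 8:12), ]
  small$label <- c(rep(0L, 7), rep(1L, 5))
  sps <- split_train_test(small, 0.75, seed = 1)
  expect_equal(unname(table(sps$train$label)), c(5L, 4L), ignore_attr = TRUE)

  one_class <- make_sep_data(3)
  one_class$label[1:5] <- 0L
  expect_error(split_train_test(one_class[1:6, ]), ">= 2 samples")
})

test_that("separable training data yields perfect training AUC and ordered scores", {
  data <- make_sep_data(15, gap = 5, noise = 0.2, seed = 7)
  model <- train_model(data, markers = "f1")
  scores <- risk_score(model, data)
  expect_true(all(scores >= 0 & scores <= 1))
  expect_equal(roc_auc(data$label, scores), 1.0)
  expect_gt(min(scores[data$label == 1]), max(scores[data$label == 0]))

  ev <- evaluate(model, data)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  expect_equal(ev$auc, 1)
  # identical samples get identical scores
  twice <- data[c(1, 1, 2), ]
  s <- risk_score(model, twice)
  expect_equal(s[1], s[2])
})

test_that("risk scores are monotone in the serialized decision value", {
  data <- make_sep_data(20, gap = 1, noise = 1, seed = 5, n_extra = 2)
  model <- train_model(data, markers = c("f1", "x1", "x2"))
  xl <- log2(errmir:::measure_matrix(data)[, model$markers] + model$log_offset)
  xs <- sweep(sweep(xl, 2, model$center), 2, model$scale, "/")
  f <- errmir:::svm_decision(model, xs)
  s <- risk_score(model, data)
  expect_equal(order(s), order(if (model$disease_first) f else -f))
})

test_that("serialized decision function reproduces e1071 probabilities", {
  data <- make_sep_data(25, gap = 2, noise = 1, seed = 9, n_extra = 2)
  model <- train_model(data, markers = c("f1", "x1", "x2"))
  xl <- log2(errmir:::measure_matrix(data)[, model$markers] + model$log_offset)
  xs <- sweep(sweep(xl, 2, model$center), 2, model$scale, "/")
  yf <- factor(ifelse(data$label == 1, "disease", "control"),
               levels = c("control", "disease"))
  refit <- withr::with_seed(1,
    e1071::svm(xs, yf, kernel = "radial", cost = model$cost,
               gamma = model$gamma, scale = FALSE, probability = TRUE))
  ref <- attr(predict(refit, xs, probability = TRUE),
              "probabilities")[, "disease"]
  expect_equal(unname(risk_score(model, data)), unname(ref),
               tolerance = 1e-10)
})

test_that("shuffled labels give chance-level cross-validated AUC", {
  withr::with_seed(31, {
    m <- cbind(f1 = 2^rnorm(200, 8, 1), f2 = 2^rnorm(200, 8, 1))
    label <- sample(rep(c(0L, 1L), each = 100))
  })
  data <- sample_table(m, label = label)
  folds <- make_cv_folds(data$label, 5, seed = 2)
  aucs <- sapply(1:5, function(f) {
    model <- train_model(data[folds != f, ], markers = c("f1", "f2"))
    ev <- evaluate(model, data[folds == f, ])
    ev$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("duplicated feature column preserves the risk ranking", {
  data <- make_sep_data(15, gap = 2, noise = 0.8, seed = 13)
  dup <- data
  dup$f1copy <- dup$f1
  m1 <- train_model(data, markers = "f1")
  m2 <- train_model(dup, markers = c("f1", "f1copy"))
  r1 <- rank(risk_score(m1, data))
  r2 <- rank(risk_score(m2, dup))
  expect_equal(r1, r2)
})

test_that("constant markers are dropped with a warning; missing markers error", {
  data <- make_sep_data(10, seed = 17)
  data$flat <- 100
  expect_warning(model <- train_model(data, markers = c("f1", "flat")),
                 "constant")
  expect_equal(model$markers, "f1")
  data$flat2 <- 1
  expect_error(
    suppressWarnings(train_model(data, markers = c("flat", "flat2"))),
    "all markers")
  expect_error(risk_score(model, data[, c("sample_id", "label", "batch", "x1")]),
               "f1")
})

test_that("trapezoidal AUC equals the rank-sum concordance estimator", {
  for (seed in 1:25) {
    withr::with_seed(seed, {
      n1 <- sample(5:30, 1); n0 <- sample(5:30, 1)
      scores <- sample(seq_len(2000), n0 + n1)  # tie-free
      labels <- c(rep(0L, n0), rep(1L, n1))
    })
    u <- sum(outer(scores[labels == 1], scores[labels == 0], ">")) / (n0 * n1)
    expect_equal(roc_auc(labels, scores), u)
  }
  # tie conventions: midranks (count 0.5); all-equal scores give 0.5
  labels <- c(0, 0, 1, 1)
  expect_equal(roc_auc(labels, c(1, 1, 1, 1)), 0.5)
  expect_equal(roc_auc(labels, c(1, 2, 2, 3)),
               (1 + 0.5 + 1 + 1) / 4)  # hand-counted concordance
})

test_that("ROC curve is a valid non-decreasing path from (0,0) to (1,1)", {
  withr::with_seed(3, {
    scores <- rnorm(40)
    labels <- rbinom(40, 1, 0.5)
  })
  labels[1:2] <- c(0L, 1L)
  rc <- roc_curve(labels, scores)
  expect_equal(rc$fpr[1], 0); expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1); expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
})

test_that("evaluation AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(8, {
    scores <- runif(30)
    labels <- rbinom(30, 1, 0.5)
  })
  labels[1:2] <- c(0L, 1L)
  a1 <- roc_auc(labels, scores)
  expect_equal(roc_auc(labels, qlogis(scores / 1.001 + 1e-4)), a1)
  expect_equal(roc_auc(labels, scores^3), a1)
  skip_if_not_installed("pROC")
  expect_equal(a1, as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                  quiet = TRUE,
                                                  direction = "<"))))
})

test_that("learning curve: separable data trains at AUC 1 and is deterministic", {
  data <- make_sep_data(24, gap = 5, noise = 0.2, seed = 21)
  lc <- suppressWarnings(learning_curve(data, markers = "f1",
                                        sizes = c(16, 32, 48),
                                        cv_folds = 4, seed = 2))
  expect_true(all(lc$train_score == 1))
  expect_true(all(diff(lc$size) > 0))
  lc2 <- suppressWarnings(learning_curve(data, markers = "f1",
                                         sizes = c(16, 32, 48),
                                         cv_folds = 4, seed = 2))
  expect_equal(as.data.frame(lc), as.data.frame(lc2))
})

test_that("one-class evaluation data raises an explicit error", {
  data <- make_sep_data(10, seed = 23)
  model <- train_model(data, markers = "f1")
  alldis <- data
  alldis$label <- 1L
  expect_error(evaluate(model, alldis), "single class")
})
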