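#' Genetic-algorithm configuration
#'
#' Defaults follow common wrapper-selection practice: a modest population
#' evolved with tournament selection, uniform crossover, per-bit mutation
#' at 1/L and single-individual elitism, with fitness equal to the mean
#' stratified cross-validated AUC of the support-vector classifier on the
#' masked feature subset, minus an optional subset-size penalty.
#'
#' @param population_size Number of chromosomes per generation.
#' @param generations Number of generations evolved.
#' @param crossover_prob Probability that a selected parent pair undergoes
#'   uniform crossover.
#' @param mutation_prob Per-bit mutation probability; `NULL` (default)
#'   means 1/L where L is the chromosome length.
#' @param tournament_size Tournament size for parent selection (>= 2).
#' @param elitism Number of top chromosomes copied unchanged.
#' @param fitness `"cv_auc"` (default) or `"cv_accuracy"`.
#' @param cv_folds Stratified cross-validation folds inside the fitness.
#' @param max_subset_penalty Penalty weight on (subset size / total).
#' @param n_repeats Number of independent GA runs for [repeat_ga()].
#' @param seed Base seed; run i uses `seed + i - 1`. The fitness fold
#'   assignment is derived from `seed` alone so all repeats share one
#'   deterministic fitness landscape.
#' @param cost,log_offset Classifier cost parameter and log2 offset used
#'   inside the fitness evaluation.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 50, generations = 40,
                      crossover_prob = 0.8, mutation_prob = NULL,
                      tournament_size = 3, elitism = 1,
                      fitness = c("cv_auc", "cv_accuracy"), cv_folds = 5,
                      max_subset_penalty = 0, n_repeats = 100, seed = 1,
                      cost = 1, log_offset = 2^-20) {
  fitness <- match.arg(fitness)
  stopifnot(population_size >= tournament_size, tournament_size >= 2,
            cv_folds >= 2, elitism >= 0, max_subset_penalty >= 0,
            crossover_prob >= 0, crossover_prob <= 1)
  structure(list(
    population_size = population_size, generations = generations,
    crossover_prob = crossover_prob, mutation_prob = mutation_prob,
    tournament_size = tournament_size, elitism = elitism,
    fitness = fitness, cv_folds = cv_folds,
    max_subset_penalty = max_subset_penalty, n_repeats = n_repeats,
    seed = seed, cost = cost, log_offset = log_offset),
    class = "ga_config")
}

#' Stratified cross-validation fold assignment
#'
#' @param labels 0/1 label vector.
#' @param k Number of folds.
#' @param seed Seed controlling the shuffle.
#' @return Integer fold id (1..k) per sample; each class is dealt
#'   round-robin after a seeded shuffle, so class proportions are
#'   preserved to rounding.
#' @export
make_cv_folds <- function(labels, k, seed = 1) {
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Cross-validated fitness of a feature subset
#'
#' Trains the radial-kernel SVM on the log2-transformed, per-fold
#' standardized subset and scores the held-out fold by AUC of the decision
#' values (or accuracy of the predicted class). The all-zero mask has
#' fitness 0 by definition.
#'
#' @param x Numeric matrix, samples x candidate features (raw values; the
#'   log2 transform is applied internally).
#' @param labels 0/1 labels.
#' @param mask Logical or 0/1 vector of length `ncol(x)`.
#' @param config A [ga_config()].
#' @param folds Fold assignment from [make_cv_folds()]; computed from
#'   `config$seed` when omitted.
#' @return Scalar fitness.
#' @export
ga_fitness <- function(x, labels, mask, config = ga_config(),
                       folds = make_cv_folds(labels, config$cv_folds,
                                             config$seed)) {
  mask <- as.logical(mask)
  if (!any(mask)) return(0)
  xm <- log2_offset(x[, mask, drop = FALSE], config$log_offset)
  scores <- purrr::map_dbl(sort(unique(folds)), function(f) {
    tr <- folds != f
    ctr <- colMeans(xm[tr, , drop = FALSE])
    scl <- apply(xm[tr, , drop = FALSE], 2, sd)
    scl[scl == 0] <- 1
    xtr <- sweep(sweep(xm[tr, , drop = FALSE], 2, ctr), 2, scl, "/")
    xte <- sweep(sweep(xm[!tr, , drop = FALSE], 2, ctr), 2, scl, "/")
    yte <- labels[!tr]
    if (length(unique(labels[tr])) < 2 || length(unique(yte)) < 2) {
      return(NA_real_)
    }
    fit <- e1071::svm(xtr, factor(labels[tr], levels = c(0, 1)),
                      kernel = "radial", cost = config$cost, scale = FALSE)
    pred <- predict(fit, xte, decision.values = TRUE)
    dv <- drop(attr(pred, "decision.values"))
    # decision values are signed toward the first libsvm label
    if (colnames(attr(pred, "decision.values"))[1] == "0/1") dv <- -dv
    if (config$fitness == "cv_auc") {
      roc_auc(yte, dv)
    } else {
      mean((dv > 0) == (yte == 1))
    }
  })
  mean(scores, na.rm = TRUE) -
    config$max_subset_penalty * sum(mask) / length(mask)
}

#' Genetic-algorithm selection of an optimal feature subset
#'
#' Evolves binary feature masks over the candidate features by tournament
#' selection, uniform crossover, per-bit mutation and elitism; fitness is
#' the cross-validated classifier score from [ga_fitness()]. The best-ever
#' chromosome is tracked across generations (ties in fitness resolved
#' toward the smaller subset, so uninformative features are not carried
#' along in the reported optimum), and with elitism >= 1 the best fitness
#' trace is non-decreasing.
#'
#' @param data Wide feature tibble with `label` metadata; the candidate
#'   features are its measurement columns (optionally restricted via
#'   `features`).
#' @param config A [ga_config()].
#' @param run_seed Seed for this run's search randomness (population
#'   initialisation, selection, crossover, mutation); defaults to
#'   `config$seed`.
#' @param features Candidate feature ids (default: all measurement columns).
#' @return List with `subset` (character feature ids), `fitness`,
#'   `trace` (best fitness per generation) and `n_evaluated` (distinct
#'   masks scored).
#' @export
ga_select <- function(data, config = ga_config(), run_seed = config$seed,
                      features = measure_cols(data)) {
  check_sample_table(data)
  if (length(features) < 2) abort("ga_select needs >= 2 candidate features")
  x <- measure_matrix(data, features)
  y <- data$label
  folds <- make_cv_folds(y, config$cv_folds, config$seed)
  L <- length(features)
  pmut <- config$mutation_prob %||% (1 / L)

  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  fit_of <- function(mask) {
    key <- paste0("m", paste(which(mask), collapse = ","))
    if (is.null(cache[[key]])) {
      cache[[key]] <- ga_fitness(x, y, mask, config, folds)
      n_eval <<- n_eval + 1L
    }
    cache[[key]]
  }

  best_mask <- NULL
  best_fit <- -Inf
  trace <- numeric(config$generations)

  withr::with_seed(run_seed, {
    pop <- matrix(rbinom(L * config$population_size, 1, 0.5) == 1,
                  nrow = config$population_size)
    for (gen in seq_len(config$generations)) {
      fits <- unname(apply(pop, 1, fit_of))
      sizes <- rowSums(pop)
      ord <- order(-fits, sizes)
      for (i in ord) {
        if (fits[i] > best_fit ||
            (fits[i] == best_fit && sum(pop[i, ]) < sum(best_mask))) {
          best_fit <- fits[i]
          best_mask <- pop[i, ]
        }
      }
      trace[gen] <- best_fit
      if (gen == config$generations) break

      new_pop <- pop[ord[seq_len(config$elitism)], , drop = FALSE]
      tournament <- function() {
        cand <- sample.int(nrow(pop), config$tournament_size)
        cand[which.max(fits[cand])]
      }
      while (nrow(new_pop) < config$population_size) {
        p1 <- pop[tournament(), ]
        p2 <- pop[tournament(), ]
        if (runif(1) < config$crossover_prob) {
          swap <- runif(L) < 0.5
          tmp <- p1[swap]; p1[swap] <- p2[swap]; p2[swap] <- tmp
        }
        for (child in list(p1, p2)) {
          flip <- runif(L) < pmut
          child[flip] <- !child[flip]
          new_pop <- rbind(new_pop, child)
          if (nrow(new_pop) >= config$population_size) break
        }
      }
      pop <- new_pop[seq_len(config$population_size), , drop = FALSE]
      rownames(pop) <- NULL
    }
  })
  list(subset = features[best_mask], fitness = best_fit, trace = trace,
       n_evaluated = n_eval)
}

#' Repeat the genetic algorithm and tally feature appearance frequencies
#'
#' Runs [ga_select()] `config$n_repeats` times with run seeds
#' `config$seed + 0 ... + n_repeats - 1` and counts, for each candidate
#' feature, the number of runs whose optimal subset contains it (one count
#' per run). Stable markers accumulate high counts; the frequency
#' distribution is typically steep when the signal is strong.
#'
#' @inheritParams ga_select
#' @return Tibble of class `errmir_freq` with `feature_id`, `count`
#'   (descending, ties broken lexicographically) and attribute
#'   `n_repeats`.
#' @export
repeat_ga <- function(data, config = ga_config(),
                      features = measure_cols(data)) {
  stopifnot(config$n_repeats >= 1)
  counts <- setNames(integer(length(features)), features)
  for (i in seq_len(config$n_repeats)) {
    res <- ga_select(data, config, run_seed = config$seed + i - 1L,
                     features = features)
    counts[res$subset] <- counts[res$subset] + 1L
  }
  out <- tibble(feature_id = features, count = as.integer(counts))
  out <- out[radix_order(-out$count, out$feature_id), ]
  attr(out, "n_repeats") <- config$n_repeats
  class(out) <- c("errmir_freq", class(out))
  out
}

#' Top-k markers from a GA frequency table
#'
#' @param freq Frequency tibble from [repeat_ga()].
#' @param k Number of markers (default 3, ties at rank k broken toward the
#'   lexicographically smaller feature id).
#' @return Character vector of up to `k` feature ids.
#' @export
top_k_markers <- function(freq, k = 3) {
  if (nrow(freq) == 0) abort("frequency table is empty")
  if (k > nrow(freq)) {
    warn(sprintf("k = %d exceeds the %d distinct features; returning all",
                 k, nrow(freq)))
    k <- nrow(freq)
  }
  ord <- freq[radix_order(-freq$count, freq$feature_id), ]
  head(ord$feature_id, k)
}
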