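#' Configuration for the synthetic multi-batch miRNA study generator
#'
#' The generator emulates the structure of multi-center small RNA-seq
#' studies: a TF-mediated regulatory network (two Bernoulli regulation
#' layers plus a precursor map), and per-batch two-group RPM-scale
#' expression matrices built on the log2 scale as
#'
#'   baseline(miRNA) + biological noise + label x effect (planted-pair
#'   numerators only) + log2 library factor(sample) + protocol bias
#'   (miRNA, batch)
#'
#' The per-sample library factor models global scale differences between
#' library preparations (it cancels in within-sample ratios); the
#' per-miRNA per-batch protocol bias models sequence-specific capture
#' differences (it does not cancel). Group-dependent signal is planted on
#' the numerator miRNA of `planted_pairs` network edges, so the
#' corresponding ratio features shift by `effect_size_log2` between groups.
#'
#' @param n_mirnas,n_tfs Numbers of miRNAs and transcription factors.
#' @param edge_prob_mirna2tf,edge_prob_tf2mirna Bernoulli edge
#'   probabilities of the two regulation layers.
#' @param n_batches Number of batches (centers / kits).
#' @param samples_per_group_per_batch Samples per group in each batch.
#' @param baseline_log2_mean,baseline_log2_sd Log2-RPM baseline abundance
#'   distribution; the defaults put ~95% of miRNAs above the 100-RPM
#'   detection filter.
#' @param bio_sd_log2 Biological (per-sample per-miRNA) noise sd on log2.
#' @param library_factor_range Per-sample library-size factor bounds
#'   (log-uniform); either one `c(low, high)` pair shared by all batches
#'   or a list of one pair per batch. Use `c(1, 1)` to disable.
#' @param protocol_bias_sd Sd (log2) of the per-miRNA per-batch bias.
#' @param planted_pairs Number of network edges carrying group signal.
#' @param effect_size_log2 Log2 shift applied to planted numerators in
#'   disease samples (default 1 = two-fold).
#' @param seed Seed; identical configs and seeds give identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_mirnas = 60, n_tfs = 15,
                       edge_prob_mirna2tf = 0.05, edge_prob_tf2mirna = 0.05,
                       n_batches = 2, samples_per_group_per_batch = 30,
                       baseline_log2_mean = 10, baseline_log2_sd = 2,
                       bio_sd_log2 = 0.5,
                       library_factor_range = c(1 / 4, 4),
                       protocol_bias_sd = 0.1,
                       planted_pairs = 5, effect_size_log2 = 1,
                       seed = 1) {
  stopifnot(n_mirnas >= 1, n_tfs >= 1,
            edge_prob_mirna2tf >= 0, edge_prob_mirna2tf <= 1,
            edge_prob_tf2mirna >= 0, edge_prob_tf2mirna <= 1,
            bio_sd_log2 >= 0, protocol_bias_sd >= 0, planted_pairs >= 0)
  if (!is.list(library_factor_range)) {
    library_factor_range <- rep(list(library_factor_range), n_batches)
  }
  stopifnot(length(library_factor_range) == n_batches)
  structure(list(
    n_mirnas = n_mirnas, n_tfs = n_tfs,
    edge_prob_mirna2tf = edge_prob_mirna2tf,
    edge_prob_tf2mirna = edge_prob_tf2mirna,
    n_batches = n_batches,
    samples_per_group_per_batch = samples_per_group_per_batch,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    bio_sd_log2 = bio_sd_log2,
    library_factor_range = library_factor_range,
    protocol_bias_sd = protocol_bias_sd,
    planted_pairs = planted_pairs,
    effect_size_log2 = effect_size_log2,
    seed = seed), class = "sim_config")
}

sim_ids <- function(prefix, n) sprintf("%s-%03d", prefix, seq_len(n))

#' Simulate the two regulation layers and a precursor map
#'
#' Draws independent Bernoulli edges miRNA -> TF and TF -> precursor, with
#' a one-to-one precursor map (`pre-<mirna>` -> mature id) so the
#' precursor-to-mature mapping step is exercised by the pipeline. Redraws
#' (bounded retries, advancing the seed) until the composed mature-level
#' network has at least `planted_pairs` edges.
#'
#' @param config A [sim_config()].
#' @param max_retries Bound on redraws (default 20).
#' @return List with tibbles `mirna_to_tf`, `tf_to_mirna` (regulator /
#'   target / source columns) and `precursor_map`.
#' @export
simulate_network <- function(config, max_retries = 20) {
  mirnas <- sim_ids("mir", config$n_mirnas)
  tfs <- sim_ids("TF", config$n_tfs)
  for (try in seq_len(max_retries)) {
    tabs <- withr::with_seed(config$seed + 7919L * (try - 1L), {
      draw_layer <- function(from, to, p, src) {
        grid <- expand.grid(regulator = from, target = to,
                            stringsAsFactors = FALSE)
        keep <- runif(nrow(grid)) < p
        tibble(regulator = grid$regulator[keep], target = grid$target[keep],
               source = src)
      }
      list(
        mirna_to_tf = draw_layer(mirnas, tfs, config$edge_prob_mirna2tf,
                                 "sim_mirna2tf"),
        tf_to_mirna = draw_layer(tfs, paste0("pre-", mirnas),
                                 config$edge_prob_tf2mirna, "sim_tf2mirna"))
    })
    tabs$precursor_map <- tibble(precursor_id = paste0("pre-", mirnas),
                                 mature_id = mirnas)
    n_edges <- tryCatch({
      net <- compose_network(tabs$mirna_to_tf, tabs$tf_to_mirna)
      nrow(map_to_mature(net, tabs$precursor_map))
    }, error = function(e) 0L)
    if (n_edges >= max(1, config$planted_pairs)) return(tabs)
  }
  abort(paste("could not realize enough composable edges for the requested",
              "planted pairs; increase the edge probabilities or network size"))
}

#' Simulate multi-batch two-group expression data with known ground truth
#'
#' @param config A [sim_config()].
#' @param network Mature-level `errmir_network` (typically composed from
#'   [simulate_network()] output); planted pairs are drawn from its edges,
#'   preferring edges whose numerator appears in no other edge and whose
#'   endpoints are detectably abundant, so each planted signal is
#'   attributable and recoverable.
#' @return List with `expression` (wide RPM tibble over all batches;
#'   samples labelled 0/1, batches `"batch1"`, ...) and `truth`, a list
#'   with `planted_pairs` (tibble feature_id/numerator/denominator),
#'   `library_factors` (named per sample) and `protocol_bias`
#'   (miRNA x batch matrix).
#' @export
simulate_expression <- function(config, network) {
  if (nrow(network) == 0) abort("network is empty")
  mirnas <- sim_ids("mir", config$n_mirnas)
  withr::with_seed(config$seed + 104729L, {
    baseline <- rnorm(config$n_mirnas, config$baseline_log2_mean,
                      config$baseline_log2_sd)
    names(baseline) <- mirnas
    # plant only on miRNAs clearing the 100-RPM detection filter with some
    # margin; signals on undetectable miRNAs would be vacuous ground truth
    detectable <- names(baseline)[baseline >= log2(100) + 0.5]
    planted <- pick_planted(network, config$planted_pairs, detectable)
    bias <- matrix(rnorm(config$n_mirnas * config$n_batches,
                         0, config$protocol_bias_sd),
                   nrow = config$n_mirnas,
                   dimnames = list(mirnas, paste0("batch",
                                                  seq_len(config$n_batches))))
    per_batch <- purrr::map(seq_len(config$n_batches), function(b) {
      n <- 2 * config$samples_per_group_per_batch
      label <- rep(c(0L, 1L), each = config$samples_per_group_per_batch)
      rng <- log2(config$library_factor_range[[b]])
      lib <- runif(n, rng[1], rng[2])
      log_expr <- matrix(baseline, nrow = n, ncol = config$n_mirnas,
                         byrow = TRUE, dimnames = list(NULL, mirnas))
      log_expr <- log_expr +
        matrix(rnorm(n * config$n_mirnas, 0, config$bio_sd_log2), nrow = n)
      if (nrow(planted) > 0) {
        log_expr[, planted$numerator] <-
          log_expr[, planted$numerator, drop = FALSE] +
          label * config$effect_size_log2
      }
      log_expr <- log_expr + lib +
        matrix(bias[, b], nrow = n, ncol = config$n_mirnas, byrow = TRUE)
      ids <- sprintf("b%d_s%03d", b, seq_len(n))
      tbl <- dplyr::bind_cols(
        tibble(sample_id = ids, label = label, batch = paste0("batch", b)),
        as_tibble(2^log_expr))
      list(tbl = tbl, lib = setNames(2^lib, ids))
    })
    expression <- bind_rows(purrr::map(per_batch, "tbl"))
    expr_unit(expression) <- "rpm"
    truth <- list(
      planted_pairs = planted,
      library_factors = unlist(unname(purrr::map(per_batch, "lib"))),
      protocol_bias = bias)
    list(expression = expression, truth = truth)
  })
}

## The group effect is applied to the planted edge's numerator miRNA, so
## every other edge incident to that miRNA would carry the same signal.
## To keep each planted signal attributable to exactly one ratio feature,
## planted edges preferentially use numerators that appear in no other
## edge (sole signal carriers); if the network is too dense to supply k
## such edges, the rule degrades to pairwise-disjoint endpoints, then to
## arbitrary edges. Endpoints are further required to be detectable
## (baseline above the abundance filter) whenever possible.
pick_planted <- function(network, k, detectable = network_nodes(network)) {
  if (k == 0) {
    return(tibble(feature_id = character(0), numerator = character(0),
                  denominator = character(0)))
  }
  if (nrow(network) < k) abort("network has fewer edges than planted_pairs")
  out_deg <- table(network$source_mirna)
  in_deg <- table(network$target_mirna)
  incident <- function(a) {
    out_deg[a] + ifelse(is.na(in_deg[a]), 0, in_deg[a])
  }
  idx <- sample(nrow(network))
  pick_with <- function(eligible) {
    chosen <- integer(0)
    used <- character(0)
    for (i in idx) {
      a <- network$source_mirna[i]; b <- network$target_mirna[i]
      if (eligible(a, b) && !(a %in% used) && !(b %in% used)) {
        chosen <- c(chosen, i)
        used <- c(used, a, b)
      }
      if (length(chosen) == k) break
    }
    chosen
  }
  seen <- function(a, b) a %in% detectable && b %in% detectable
  chosen <- pick_with(function(a, b) incident(a) == 1 && seen(a, b))
  if (length(chosen) < k) chosen <- pick_with(seen)
  if (length(chosen) < k) chosen <- pick_with(function(a, b) TRUE)
  if (length(chosen) < k) chosen <- idx[seq_len(k)]
  sel <- network[sort(chosen), ]
  tibble(feature_id = paste(sel$source_mirna, sel$target_mirna, sep = "|"),
         numerator = sel$source_mirna, denominator = sel$target_mirna)
}

#' One-call synthetic study: network plus expression
#'
#' Convenience wrapper chaining [simulate_network()], network composition,
#' precursor mapping and [simulate_expression()].
#'
#' @param config A [sim_config()].
#' @return List with `network` (mature-level `errmir_network`), `tables`
#'   (the raw regulation tables and precursor map), `expression` and
#'   `truth`.
#' @export
simulate_study <- function(config = sim_config()) {
  tabs <- simulate_network(config)
  net <- suppressWarnings(
    compose_network(tabs$mirna_to_tf, tabs$tf_to_mirna))
  net <- suppressMessages(map_to_mature(net, tabs$precursor_map))
  sim <- simulate_expression(config, net)
  list(network = net, tables = tabs, expression = sim$expression,
       truth = sim$truth)
}
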