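# Shared fixture builders; everything is generated in code under fixed seeds.

reg_tbl <- function(regulator, target, source = "test") {
  tibble::tibble(regulator = regulator, target = target, source = source)
}

# Random regulation layers over n miRNAs / t TFs with edge probability p.
random_layers <- function(n_mirnas, n_tfs, p, seed) {
  withr::with_seed(seed, {
    mirnas <- sprintf("m%02d", seq_len(n_mirnas))
    tfs <- sprintf("T%02d", seq_len(n_tfs))
    g1 <- expand.grid(regulator = mirnas, target = tfs,
                      stringsAsFactors = FALSE)
    g2 <- expand.grid(regulator = tfs, target = mirnas,
                      stringsAsFactors = FALSE)
    list(mirna_to_tf = tibble::as_tibble(g1[runif(nrow(g1)) < p, ]),
         tf_to_mirna = tibble::as_tibble(g2[runif(nrow(g2)) < p, ]))
  })
}

# Exhaustive (a, t, b) triple-loop join oracle, independent of
# compose_network's join machinery.
oracle_compose <- function(mirna_to_tf, tf_to_mirna) {
  out <- list()
  for (i in seq_len(nrow(mirna_to_tf))) {
    a <- mirna_to_tf$regulator[i]
    t1 <- mirna_to_tf$target[i]
    for (j in seq_len(nrow(tf_to_mirna))) {
      if (tf_to_mirna$regulator[j] == t1) {
        b <- tf_to_mirna$target[j]
        if (a != b) {
          key <- paste(a, b, sep = "\r")
          out[[key]] <- sort(unique(c(out[[key]], t1)))
        }
      }
    }
  }
  if (length(out) == 0) return(NULL)
  keys <- sort(names(out), method = "radix")
  parts <- strsplit(keys, "\r", fixed = TRUE)
  tibble::tibble(
    source_mirna = vapply(parts, `[`, "", 1),
    target_mirna = vapply(parts, `[`, "", 2),
    mediators = unname(out[keys]))
}

# Wide sample table from a samples x variables matrix.
sample_table <- function(m, label = NULL, batch = "batch1",
                         ids = sprintf("s%03d", seq_len(nrow(m)))) {
  label <- label %||% rep(0L, nrow(m))
  dplyr::bind_cols(
    tibble::tibble(sample_id = ids, label = as.integer(label),
                   batch = rep_len(batch, nrow(m))),
    tibble::as_tibble(m))
}

# Tiny line network a -> b -> c ... over the given node ids.
chain_network <- function(nodes, tf = "T1") {
  edges <- tibble::tibble(
    source_mirna = head(nodes, -1),
    target_mirna = nodes[-1],
    mediators = rep(list(tf), length(nodes) - 1))
  errmir:::new_network(edges)
}

`%||%` <- rlang::`%||%`
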