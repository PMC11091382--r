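#' Compose the TF-mediated miRNA-miRNA interaction network
#'
#' Joins two regulation layers into a directed miRNA-miRNA network: an edge
#' a -> b exists whenever some transcription factor t is targeted by miRNA a
#' (first layer) and itself regulates miRNA b (second layer). The set of all
#' such mediating TFs is kept on the edge. Self-loops (a == b) are dropped
#' and duplicate (a, b) records are merged by taking the union of their
#' mediators.
#'
#' The default `join_mode = "chain"` is the a -> TF -> b chain described
#' above. `join_mode = "co_target"` instead connects a -> b when a TF
#' targeted by miRNA a is also targeted by miRNA b in the first layer
#' (a co-targeting reading of "a regulated a TF that was regulated by b");
#' it only uses the miRNA -> TF layer.
#'
#' @param mirna_to_tf Tibble/data frame of miRNA -> TF regulations with
#'   columns `regulator` (miRNA) and `target` (TF).
#' @param tf_to_mirna Tibble of TF -> miRNA regulations with columns
#'   `regulator` (TF) and `target` (miRNA). Ignored for
#'   `join_mode = "co_target"`.
#' @param join_mode Either `"chain"` (default) or `"co_target"`.
#' @return A tibble of class `errmir_network` with columns `source_mirna`,
#'   `target_mirna` and a list-column `mediators` (character vectors of TF
#'   ids), sorted lexicographically by (source, target).
#' @export
compose_network <- function(mirna_to_tf, tf_to_mirna,
                            join_mode = c("chain", "co_target")) {
  join_mode <- match.arg(join_mode)
  check_regulation(mirna_to_tf, "mirna_to_tf")
  if (join_mode == "chain") check_regulation(tf_to_mirna, "tf_to_mirna")

  if (join_mode == "chain") {
    mirna_side <- union(mirna_to_tf$regulator, tf_to_mirna$target)
    tf_side <- union(mirna_to_tf$target, tf_to_mirna$regulator)
    shared <- intersect(mirna_side, tf_side)
    if (length(shared) > 0) {
      warn(sprintf(
        "%d identifier(s) appear as both miRNA and TF (e.g. %s); records kept",
        length(shared), shared[1]))
    }
    joined <- dplyr::inner_join(
      dplyr::distinct(tibble(a = mirna_to_tf$regulator, tf = mirna_to_tf$target)),
      dplyr::distinct(tibble(tf = tf_to_mirna$regulator, b = tf_to_mirna$target)),
      by = "tf", relationship = "many-to-many")
  } else {
    layer <- dplyr::distinct(
      tibble(mirna = mirna_to_tf$regulator, tf = mirna_to_tf$target))
    joined <- dplyr::inner_join(
      dplyr::rename(layer, a = "mirna"),
      dplyr::rename(layer, b = "mirna"),
      by = "tf", relationship = "many-to-many")
  }

  joined <- dplyr::filter(joined, .data$a != .data$b)
  if (nrow(joined) == 0) {
    abort("no edges composable from the supplied regulation layers")
  }
  edges <- joined |>
    group_by(source_mirna = .data$a, target_mirna = .data$b) |>
    summarise(mediators = list(radix_sort(unique(.data$tf))), .groups = "drop")
  new_network(edges)
}

check_regulation <- function(x, arg) {
  if (!all(c("regulator", "target") %in% names(x))) {
    abort(sprintf("`%s` must have columns `regulator` and `target`", arg))
  }
  if (nrow(x) == 0) abort(sprintf("`%s` is empty: no edges composable", arg))
  if (any(x$regulator == "" | x$target == "" |
          is.na(x$regulator) | is.na(x$target))) {
    abort(sprintf("`%s` contains empty or missing identifiers", arg))
  }
  invisible(x)
}

new_network <- function(edges) {
  edges <- edges[radix_order(edges$source_mirna, edges$target_mirna), ]
  edges <- as_tibble(edges)
  class(edges) <- c("errmir_network", class(edges))
  edges
}

#' @export
print.errmir_network <- function(x, ...) {
  cat(sprintf("# ERRmiR interaction network: %d nodes, %d directed edges\n",
              length(network_nodes(x)), nrow(x)))
  NextMethod()
}

#' Nodes of a miRNA interaction network
#'
#' @param network An `errmir_network` tibble.
#' @return Sorted character vector of miRNA ids.
#' @export
network_nodes <- function(network) {
  radix_sort(unique(c(network$source_mirna, network$target_mirna)))
}

#' Map network endpoints from precursor to mature miRNA identifiers
#'
#' Each endpoint that appears in the precursor map is expanded to all of its
#' mature forms (the edge becomes the cross-product of the two expansions);
#' endpoints absent from the map pass through unchanged on the side that is
#' already mature. An edge whose precursor endpoint has no mature form is
#' dropped and counted. Duplicate mature edges are merged by union of
#' mediators and self-loops are removed.
#'
#' @param network An `errmir_network` whose endpoints may be precursor ids.
#' @param pmap Tibble with columns `precursor_id`, `mature_id` (a precursor
#'   may repeat across rows, one mature form per row).
#' @param strict If `TRUE`, endpoints not found in `pmap` are treated as
#'   precursors without mature forms and their edges dropped; the default
#'   (`FALSE`) passes unmapped endpoints through as already-mature ids.
#' @return A mature-level `errmir_network`; the number of dropped edges is
#'   available as `attr(result, "n_dropped")` and reported via a message.
#' @export
map_to_mature <- function(network, pmap, strict = FALSE) {
  if (!all(c("precursor_id", "mature_id") %in% names(pmap))) {
    abort("`pmap` must have columns `precursor_id` and `mature_id`")
  }
  lookup <- split(pmap$mature_id, pmap$precursor_id)
  expand <- function(id) {
    hit <- lookup[[id]]
    if (!is.null(hit)) unique(hit) else if (strict) character(0) else id
  }
  rows <- purrr::pmap(
    list(network$source_mirna, network$target_mirna, network$mediators),
    function(a, b, meds) {
      ma <- expand(a); mb <- expand(b)
      if (length(ma) == 0 || length(mb) == 0) return(NULL)
      grid <- expand.grid(source_mirna = ma, target_mirna = mb,
                          stringsAsFactors = FALSE)
      grid$mediators <- rep(list(meds), nrow(grid))
      grid
    })
  dropped <- sum(purrr::map_lgl(rows, is.null))
  if (dropped > 0) {
    inform(sprintf("map_to_mature: dropped %d edge(s) with unmapped precursor endpoints",
                   dropped))
  }
  out <- bind_rows(rows)
  out <- dplyr::filter(out, .data$source_mirna != .data$target_mirna)
  if (nrow(out) == 0) abort("no edges remain after precursor-to-mature mapping")
  out <- out |>
    group_by(.data$source_mirna, .data$target_mirna) |>
    summarise(mediators = list(radix_sort(unique(unlist(.data$mediators)))),
              .groups = "drop")
  out <- new_network(out)
  attr(out, "n_dropped") <- dropped
  out
}

#' Edges whose endpoints both lie in a retained miRNA set
#'
#' @param network An `errmir_network`.
#' @param retained Character vector of miRNA ids (typically the set passing
#'   the abundance filter).
#' @return The sub-network of directed edges with both endpoints retained,
#'   in lexicographic (source, target) order; may be empty.
#' @export
connected_pairs <- function(network, retained) {
  keep <- network$source_mirna %in% retained & network$target_mirna %in% retained
  new_network(network[keep, , drop = FALSE])
}
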