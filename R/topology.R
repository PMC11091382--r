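#' Topological summary of a miRNA interaction network
#'
#' Degree statistics are computed on the undirected projection of the
#' directed network (reciprocal edges collapse to one undirected edge).
#' The power-law exponent is the negative slope of a least-squares fit of
#' log(count) on log(degree) over the observed degree histogram (degrees
#' >= 1 with count >= 1); scale-free networks show exponents around 2-3.
#' Average clustering (mean local clustering coefficient, isolated and
#' degree-1 nodes contributing 0) and average shortest path length are
#' computed on the largest connected component, the conventional
#' small-world diagnostics.
#'
#' @param network An `errmir_network`.
#' @return A one-row tibble with `n_nodes`, `n_edges` (directed),
#'   `powerlaw_exponent`, `avg_clustering`, `avg_shortest_path` (NA for a
#'   single-node component) and a list-column `degree_histogram`
#'   (tibble of `degree`, `count`).
#' @export
topology_stats <- function(network) {
  if (nrow(network) == 0) abort("network is empty")
  g <- network_igraph(network, directed = FALSE)
  deg <- igraph::degree(g)
  hist_tbl <- tibble(degree = as.integer(names(table(deg))),
                     count = as.integer(table(deg)))

  fit_tbl <- dplyr::filter(hist_tbl, .data$degree >= 1)
  exponent <- if (nrow(fit_tbl) >= 2) {
    -unname(stats::coef(stats::lm(log(count) ~ log(degree), data = fit_tbl))[2])
  } else NA_real_
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  avg_path <- if (igraph::vcount(giant) > 1) {
    igraph::mean_distance(giant, directed = FALSE)
  } else NA_real_
  cl <- igraph::transitivity(giant, type = "localaverage", isolates = "zero")

  tibble(
    n_nodes = igraph::vcount(g),
    n_edges = nrow(network),
    powerlaw_exponent = exponent,
    avg_clustering = cl,
    avg_shortest_path = avg_path,
    degree_histogram = list(hist_tbl)
  )
}

## Undirected projection used for all topology metrics.
network_igraph <- function(network, directed = TRUE) {
  igraph::graph_from_data_frame(
    data.frame(from = network$source_mirna, to = network$target_mirna),
    directed = directed,
    vertices = network_nodes(network)) |>
    (\(g) if (directed) g else igraph::simplify(igraph::as_undirected(g)))()
}
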