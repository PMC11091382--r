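test_that("minimal joins, mediator merging and self-loop exclusion", {
  net <- compose_network(reg_tbl("a", "t1"), reg_tbl("t1", "b"))
  expect_equal(net$source_mirna, "a")
  expect_equal(net$target_mirna, "b")
  expect_equal(net$mediators, list("t1"))

  # two mediating TFs collapse onto one edge
  net2 <- compose_network(reg_tbl(c("a", "a"), c("t1", "t2")),
                          reg_tbl(c("t1", "t2"), c("b", "b")))
  expect_equal(nrow(net2), 1)
  expect_equal(net2$mediators[[1]], c("t1", "t2"))

  # a -> t1 -> a is a self-loop and is dropped entirely
  expect_error(compose_network(reg_tbl("a", "t1"), reg_tbl("t1", "a")),
               "no edges composable")

  expect_error(compose_network(reg_tbl(character(0), character(0)),
                               reg_tbl("t1", "b")),
               "empty")
})

test_that("identifier shared between miRNA and TF namespaces warns but keeps records", {
  # "x" is a miRNA in layer 1 and a TF in layer 2
  expect_warning(
    net <- compose_network(reg_tbl(c("a", "x"), c("t1", "t1")),
                           reg_tbl(c("t1", "x"), c("b", "c"))),
    "both miRNA and TF")
  expect_setequal(paste(net$source_mirna, net$target_mirna),
                  c("a b", "x b"))
})

test_that("compose_network matches the exhaustive triple-join oracle on random instances", {
  for (seed in 1:20) {
    layers <- random_layers(n_mirnas = 30, n_tfs = 10, p = 0.08, seed = seed)
    expected <- oracle_compose(layers$mirna_to_tf, layers$tf_to_mirna)
    if (is.null(expected)) {
      expect_error(compose_network(layers$mirna_to_tf, layers$tf_to_mirna),
                   "no edges composable")
    } else {
      got <- compose_network(layers$mirna_to_tf, layers$tf_to_mirna)
      expect_equal(as.data.frame(got[1:3]), as.data.frame(expected),
                   ignore_attr = TRUE)
    }
  }
})

test_that("adding regulation records never removes composed edges", {
  layers <- random_layers(25, 8, 0.12, seed = 42)
  net_full <- compose_network(layers$mirna_to_tf, layers$tf_to_mirna)
  reduced <- layers$mirna_to_tf[-seq_len(5), ]
  net_red <- tryCatch(compose_network(reduced, layers$tf_to_mirna),
                      error = function(e) NULL)
  key <- function(n) paste(n$source_mirna, n$target_mirna)
  if (!is.null(net_red)) {
    expect_true(all(key(net_red) %in% key(net_full)))
  }
})

test_that("co-target join mode connects miRNAs sharing a targeted TF", {
  m2t <- reg_tbl(c("a", "b", "c"), c("t1", "t1", "t2"))
  net <- compose_network(m2t, reg_tbl("tX", "zzz"), join_mode = "co_target")
  expect_setequal(paste(net$source_mirna, net$target_mirna),
                  c("a b", "b a"))
})

test_that("map_to_mature expands cross-products, merges mediators, drops unmapped", {
  net <- errmir:::new_network(tibble::tibble(
    source_mirna = c("pre-x", "pre-z"),
    target_mirna = c("pre-y", "pre-y"),
    mediators = list("t1", "t2")))
  pmap <- tibble::tibble(
    precursor_id = c("pre-x", "pre-x", "pre-y"),
    mature_id = c("x-5p", "x-3p", "y-5p"))

  mature <- suppressMessages(map_to_mature(net, pmap, strict = TRUE))
  expect_setequal(paste(mature$source_mirna, mature$target_mirna),
                  c("x-5p y-5p", "x-3p y-5p"))
  expect_equal(attr(mature, "n_dropped"), 1)

  # two precursor edges collapsing onto one mature pair: mediators unioned
  net2 <- errmir:::new_network(tibble::tibble(
    source_mirna = c("pre-x", "pre-w"),
    target_mirna = c("pre-y", "pre-y"),
    mediators = list("t1", "t2")))
  pmap2 <- tibble::tibble(precursor_id = c("pre-x", "pre-w", "pre-y"),
                          mature_id = c("x", "x", "y"))
  mature2 <- map_to_mature(net2, pmap2)
  expect_equal(nrow(mature2), 1)
  expect_equal(mature2$mediators[[1]], c("t1", "t2"))
})

test_that("map_to_mature equals a brute-force expand-then-dedupe oracle", {
  withr::with_seed(7, {
    nodes <- sprintf("pre-%02d", 1:12)
    edges <- expand.grid(a = nodes, b = nodes, stringsAsFactors = FALSE)
    edges <- edges[edges$a != edges$b & runif(nrow(edges)) < 0.15, ]
    net <- errmir:::new_network(tibble::tibble(
      source_mirna = edges$a, target_mirna = edges$b,
      mediators = lapply(seq_len(nrow(edges)),
                         function(i) sample(c("t1", "t2", "t3"),
                                            sample(1:2, 1)))))
    pmap <- tibble::tibble(
      precursor_id = rep(nodes, times = rep_len(1:2, length(nodes))),
      mature_id = paste0("mat-", seq_len(18)))
  })
  got <- suppressMessages(map_to_mature(net, pmap, strict = TRUE))

  # oracle: explicit loop expansion, then dedupe by union
  acc <- list()
  lookup <- split(pmap$mature_id, pmap$precursor_id)
  for (i in seq_len(nrow(net))) {
    for (ma in lookup[[net$source_mirna[i]]]) {
      for (mb in lookup[[net$target_mirna[i]]]) {
        if (ma != mb) {
          key <- paste(ma, mb, sep = "\r")
          acc[[key]] <- sort(unique(c(acc[[key]], net$mediators[[i]])))
        }
      }
    }
  }
  keys <- sort(names(acc), method = "radix")
  expect_equal(paste(got$source_mirna, got$target_mirna, sep = "\r"), keys)
  expect_equal(got$mediators, unname(acc[keys]))

  # mediator multiset conservation for a single precursor edge
  one <- errmir:::new_network(net[1, ])
  gone <- suppressMessages(map_to_mature(one, pmap, strict = TRUE))
  for (m in gone$mediators) expect_equal(m, sort(net$mediators[[1]]))
})

test_that("connected_pairs filters edges by retained endpoints", {
  layers <- random_layers(20, 6, 0.15, seed = 3)
  net <- compose_network(layers$mirna_to_tf, layers$tf_to_mirna)
  expect_equal(connected_pairs(net, network_nodes(net)), net)
  expect_equal(nrow(connected_pairs(net, character(0))), 0)

  withr::with_seed(5, keep <- sample(network_nodes(net), 8))
  got <- connected_pairs(net, keep)
  manual <- net[net$source_mirna %in% keep & net$target_mirna %in% keep, ]
  expect_equal(as.data.frame(got), as.data.frame(manual), ignore_attr = TRUE)
})

test_that("topology closed forms hold for star and clique", {
  star <- chain_network(c("hub", "x"))  # placeholder, rebuilt below
  star <- errmir:::new_network(tibble::tibble(
    source_mirna = "hub", target_mirna = paste0("leaf", 1:4),
    mediators = rep(list("t"), 4)))
  ts <- topology_stats(star)
  hist <- ts$degree_histogram[[1]]
  expect_equal(hist$count[hist$degree == 4], 1)
  expect_equal(hist$count[hist$degree == 1], 4)
  expect_equal(ts$avg_clustering, 0)

  nodes <- paste0("n", 1:4)
  grid <- expand.grid(a = nodes, b = nodes, stringsAsFactors = FALSE)
  grid <- grid[grid$a != grid$b, ]
  clique <- errmir:::new_network(tibble::tibble(
    source_mirna = grid$a, target_mirna = grid$b,
    mediators = rep(list("t"), nrow(grid))))
  tc <- topology_stats(clique)
  expect_equal(tc$avg_clustering, 1)
  expect_equal(tc$avg_shortest_path, 1)
  expect_equal(sum(tc$degree_histogram[[1]]$count), tc$n_nodes)
})

test_that("average shortest path matches an all-pairs BFS oracle", {
  layers <- random_layers(50, 15, 0.05, seed = 11)
  net <- compose_network(layers$mirna_to_tf, layers$tf_to_mirna)
  ts <- topology_stats(net)

  # BFS oracle on the undirected projection's largest component
  nodes <- network_nodes(net)
  adj <- lapply(setNames(nodes, nodes), function(v) character(0))
  for (i in seq_len(nrow(net))) {
    a <- net$source_mirna[i]; b <- net$target_mirna[i]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  bfs <- function(start) {
    dist <- setNames(rep(NA_real_, length(nodes)), nodes)
    dist[start] <- 0
    queue <- start
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
    dist
  }
  comp_sizes <- sapply(nodes, function(v) sum(!is.na(bfs(v))))
  giant <- nodes[!is.na(bfs(nodes[which.max(comp_sizes)]))]
  dists <- unlist(lapply(giant, function(v) bfs(v)[setdiff(giant, v)]))
  expect_equal(ts$avg_shortest_path, mean(dists))
})
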