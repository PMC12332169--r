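line_network <- function(genes) {
  interaction_network(data.frame(source = genes[-length(genes)],
                                 target = genes[-1], confidence = 1))
}

test_that("edge costs follow the inverted geometric mean", {
  net <- line_network(c("A", "B", "C", "D"))
  w_eq <- setNames(rep(2, 4), c("A", "B", "C", "D"))
  pg <- build_path_graph(net, w_eq)
  expect_equal(igraph::E(pg$graph)$cost, rep(1, 3))  # what == 1 everywhere

  w <- c(A = 4, B = 1, C = 1, D = 4)
  pg <- build_path_graph(net, w)
  # what = (1, .25, .25, 1); cost(A,B) = 1/sqrt(1 * 0.25) = 2
  el <- igraph::as_edgelist(pg$graph)
  ab <- which(el[, 1] == "A" & el[, 2] == "B" |
              el[, 1] == "B" & el[, 2] == "A")
  expect_equal(igraph::E(pg$graph)$cost[ab], 2)

  # scaling all weights leaves costs unchanged
  pg2 <- build_path_graph(net, w * 2)
  expect_equal(igraph::E(pg2$graph)$cost, igraph::E(pg$graph)$cost)

  expect_error(build_path_graph(net, c(X = 1)), "no overlap")
  expect_error(build_path_graph(net, c(A = -1, B = 1)), "strictly positive")
})

test_that("candidate_paths returns minimum-cost paths between terminals", {
  net <- line_network(c("A", "B"))
  pg <- build_path_graph(net, c(A = 1, B = 1))
  cp <- candidate_paths(pg, terminal_fraction = 1)
  expect_equal(nrow(cp), 2)  # both ordered pairs of the one edge
  expect_equal(cp$cost, igraph::E(pg$graph)$cost[c(1, 1)])

  pg2 <- build_path_graph(line_network(c("A", "B", "C")),
                          c(A = 1, B = 1, C = 1))
  expect_error(candidate_paths(pg2, terminals = "A"), ">= 2 terminal")
})

test_that("Dijkstra agrees with exhaustive enumeration on small graphs", {
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(4:8, 1)
    net <- random_test_network(n, sample((n - 1):(n * 2), 1), seed)
    genes <- network_genes(net)
    w <- setNames(runif(length(genes), 0.05, 1), genes)
    pg <- build_path_graph(net, w)
    cp <- tryCatch(candidate_paths(pg, terminal_fraction = 0.5),
                   error = function(e) NULL)
    if (is.null(cp)) next
    adj <- edges_to_adj(net$edges, genes)
    for (i in seq_len(nrow(cp))) {
      oracle <- enum_min_path_cost(adj, pg$what, cp$source[i], cp$target[i])
      expect_equal(cp$cost[i], oracle, tolerance = 1e-9)
    }
  }
})

test_that("uniform weights make every permutation tie: p = 1", {
  net <- random_test_network(10, 15, seed = 2)
  genes <- network_genes(net)
  pg <- build_path_graph(net, setNames(rep(1, length(genes)), genes))
  cp <- candidate_paths(pg, terminal_fraction = 0.4)
  cp <- permutation_significance(pg, cp, n_perm = 20, seed = 1)
  expect_equal(cp$p_value, rep(1, nrow(cp)))
  expect_error(permutation_significance(pg, cp, n_perm = 20, seed = NULL),
               "seed")
})

test_that("plus-one estimator bounds p in [1/(B+1), 1] on a grid", {
  net <- random_test_network(30, 60, seed = 5)
  genes <- network_genes(net)
  set.seed(5)
  pg <- build_path_graph(net, setNames(runif(length(genes), 0.1, 1), genes))
  cp <- candidate_paths(pg, terminal_fraction = 0.2)
  cp <- permutation_significance(pg, cp, n_perm = 50, seed = 9)
  expect_true(all(cp$p_value >= 1 / 51 & cp$p_value <= 1))
  expect_equal(cp$p_value * 51, round(cp$p_value * 51))
})

test_that("permutation p-values are invariant to gene relabelling", {
  net <- random_test_network(15, 25, seed = 11)
  genes <- network_genes(net)
  set.seed(11)
  w <- setNames(runif(length(genes), 0.1, 1), genes)
  run <- function(net, w) {
    pg <- build_path_graph(net, w)
    cp <- candidate_paths(pg, terminal_fraction = 0.3)
    sort(permutation_significance(pg, cp, n_perm = 30, seed = 4)$p_value)
  }
  p1 <- run(net, w)
  relabel <- setNames(sprintf("z%02d", seq_along(genes)), genes)
  net2 <- interaction_network(data.frame(
    source = unname(relabel[net$edges$source]),
    target = unname(relabel[net$edges$target]),
    confidence = net$edges$confidence))
  w2 <- setNames(w, unname(relabel[names(w)]))
  expect_equal(p1, run(net2, w2))
})

make_paths <- function(paths, p) {
  df <- data.frame(source = vapply(paths, `[`, "", 1),
                   target = vapply(paths, function(x) x[length(x)], ""),
                   cost = 1, p_value = p, stringsAsFactors = FALSE)
  structure(df, paths = paths,
            terminals = unique(unlist(paths)),
            class = c("CandidatePaths", "data.frame"))
}

test_that("build_topnet unions significant path edges", {
  cp <- make_paths(list(c("a", "b", "c")), p = 0.004)
  tn <- build_topnet(cp, alpha = 0.05)
  expect_equal(length(tn$nodes), 3)
  expect_equal(nrow(tn$edges), 2)

  # all p = 1 -> empty TopNet with a warning
  cp1 <- make_paths(list(c("a", "b", "c")), p = 1)
  expect_warning(tn1 <- build_topnet(cp1), "empty")
  expect_length(tn1$nodes, 0)

  # overlapping paths collapse duplicate edges
  cp2 <- make_paths(list(c("a", "b", "c"), c("a", "b", "d")),
                    p = c(0.001, 0.001))
  tn2 <- build_topnet(cp2)
  expect_equal(nrow(tn2$edges), 3)
  expect_lte(nrow(tn2$edges), 4)  # <= sum of path lengths
})

test_that("ripple centrality matches hand values and the closure oracle", {
  tn <- build_topnet(make_paths(list(c("a", "b", "c")), 0.001))
  r <- ripple_centrality(tn)
  expect_equal(unname(r["b"]), 0.5)   # sqrt(1 * 1) / 2
  expect_equal(unname(r["a"]), 0)     # reaches 2, reached by 0
  expect_equal(unname(r["c"]), 0)

  # complete bidirectional graph: r == 1 everywhere
  nodes <- letters[1:4]
  pairs <- expand.grid(from = nodes, to = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  tnc <- structure(list(
    nodes = nodes, edges = pairs,
    graph = igraph::graph_from_data_frame(pairs, vertices = nodes)),
    class = "TopNet")
  expect_equal(unname(ripple_centrality(tnc)), rep(1, 4))

  # closure oracle on random DAGs
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(4:10, 1)
    nodes <- sprintf("v%02d", 1:n)
    pairs <- t(utils::combn(nodes, 2))  # i < j: acyclic by construction
    pick <- sample(nrow(pairs), min(nrow(pairs), n * 2), replace = FALSE)
    edges <- data.frame(from = pairs[pick, 1], to = pairs[pick, 2],
                        stringsAsFactors = FALSE)
    tn <- structure(list(nodes = nodes, edges = edges,
                         graph = igraph::graph_from_data_frame(
                           edges, vertices = nodes)),
                    class = "TopNet")
    r <- ripple_centrality(tn)
    o <- closure_reach(edges, nodes)
    expect_equal(r, sqrt(o$out * o$inn) / (n - 1), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("raising a non-maximal node weight cannot raise costs through it", {
  net <- random_test_network(12, 24, seed = 13)
  genes <- network_genes(net)
  set.seed(13)
  w <- setNames(runif(length(genes), 0.1, 0.5), genes)
  w[1] <- 1  # fixed maximum
  pg1 <- build_path_graph(net, w)
  v <- genes[3]
  w2 <- w; w2[v] <- w2[v] * 1.5  # still below the max
  pg2 <- build_path_graph(net, w2)
  el <- igraph::as_edgelist(pg1$graph)
  through <- el[, 1] == v | el[, 2] == v
  expect_true(all(igraph::E(pg2$graph)$cost[through] <=
                  igraph::E(pg1$graph)$cost[through] + 1e-12))
})
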