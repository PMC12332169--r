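# Differentially active paths on a node-weighted interactome.
#
# Node weights are normalised by their maximum (w-hat in (0,1]) and an edge
# u-v costs 1/sqrt(w-hat_u * w-hat_v): the inverted geometric mean, so a
# path is cheap only if every node along it carries high weight.  The
# minimum-cost paths between high-weight terminal genes are scored against
# a null that shuffles the node weights over the network (topology fixed,
# weight placement tested), and the union of significant paths is the
# per-sample TopNet.  Ripple centrality then ranks TopNet genes by how many
# nodes they can reach and be reached from.

#' Build a node-weighted path graph
#'
#' @param network an [interaction_network()].
#' @param weights a `NodeWeightVector` from [residual_weights()] or a named
#'   strictly positive numeric vector.  Network genes absent from the
#'   weights get the floor `eps`.
#' @param eps floor for unweighted network genes (taken from the weight
#'   vector when available).
#' @return A `WeightedPathGraph`: list with `graph` (igraph, edge attribute
#'   `cost`), `nodes`, `w` (raw weights), `what` (normalised weights),
#'   `directed`.
#' @export
build_path_graph <- function(network, weights, eps = 1e-4) {
  stopifnot(inherits(network, "InteractionNetwork"))
  if (inherits(weights, "NodeWeightVector")) {
    eps <- weights$eps
    weights <- weights$weights
  }
  if (is.null(names(weights)) || any(weights <= 0))
    stop("weights must be a named, strictly positive vector")
  nodes <- network_genes(network)
  if (!length(intersect(nodes, names(weights))))
    stop("no overlap between weighted genes and network nodes")
  w <- stats::setNames(rep(eps, length(nodes)), nodes)
  known <- intersect(nodes, names(weights))
  w[known] <- weights[known]
  what <- w / max(w)
  g <- igraph::graph_from_data_frame(network$edges[, c("source", "target")],
                                     directed = network$directed,
                                     vertices = nodes)
  igraph::E(g)$cost <- edge_costs(g, what)
  structure(list(graph = g, nodes = nodes, w = w, what = what,
                 directed = network$directed),
            class = "WeightedPathGraph")
}

#' Edge costs 1/sqrt(what_u * what_v) for an igraph with named vertices
#' @noRd
edge_costs <- function(g, what) {
  el <- igraph::as_edgelist(g, names = TRUE)
  1 / sqrt(what[el[, 1]] * what[el[, 2]])
}

#' @exportS3Method base::print
print.WeightedPathGraph <- function(x, ...) {
  cat(sprintf("WeightedPathGraph: %d nodes, %d edges, costs in [%.3g, %.3g]\n",
              length(x$nodes), igraph::ecount(x$graph),
              min(igraph::E(x$graph)$cost), max(igraph::E(x$graph)$cost)))
  invisible(x)
}

#' Terminal genes: the top fraction of nodes by weight
#' @noRd
path_terminals <- function(pg, terminal_fraction) {
  stopifnot(terminal_fraction > 0, terminal_fraction <= 1)
  n_term <- max(2, ceiling(terminal_fraction * length(pg$nodes)))
  ord <- order(-pg$w, pg$nodes)
  pg$nodes[ord[seq_len(min(n_term, length(pg$nodes)))]]
}

#' Minimum-cost paths between high-weight terminal genes
#'
#' Terminals are the top `terminal_fraction` of nodes by weight (ties by
#' gene ID).  For every ordered terminal pair the minimum-cost (Dijkstra)
#' path is returned; unreachable pairs are skipped.
#'
#' @param pg a [build_path_graph()] result.
#' @param terminal_fraction fraction of nodes used as terminals (default
#'   0.05).
#' @param terminals optional explicit terminal genes, overriding the
#'   weight-based selection.  Calibration studies should pass terminals
#'   chosen independently of the weights: weight-selected terminals make
#'   observed paths cheap by construction, which is the signal the
#'   permutation test is designed to detect.
#' @param pairs optional two-column character matrix of explicit ordered
#'   (source, target) pairs; overrides both terminal selections.
#' @return A `CandidatePaths` object: data frame with columns `source`,
#'   `target`, `cost`, plus a `paths` attribute (list of gene vectors,
#'   aligned to rows) and a `terminals` attribute.
#' @export
candidate_paths <- function(pg, terminal_fraction = 0.05,
                            terminals = NULL, pairs = NULL) {
  stopifnot(inherits(pg, "WeightedPathGraph"))
  if (!is.null(pairs)) {
    stopifnot(is.matrix(pairs), ncol(pairs) == 2,
              all(pairs %in% pg$nodes), all(pairs[, 1] != pairs[, 2]))
    terms <- sort(unique(as.vector(pairs)))
  } else {
    terms <- if (is.null(terminals)) path_terminals(pg, terminal_fraction)
             else {
               stopifnot(all(terminals %in% pg$nodes))
               unique(terminals)
             }
    if (length(terms) < 2) stop("need >= 2 terminal genes")
  }
  rows <- list(); paths <- list(); k <- 0L
  cost <- igraph::E(pg$graph)$cost
  sources <- if (is.null(pairs)) terms else unique(pairs[, 1])
  for (s in sources) {
    to_s <- if (is.null(pairs)) setdiff(terms, s)
            else unique(pairs[pairs[, 1] == s, 2])
    sp <- igraph::shortest_paths(pg$graph, from = s, to = to_s,
                                 mode = "out", weights = cost,
                                 output = "vpath")
    for (vp in sp$vpath) {
      if (length(vp) < 2) next  # unreachable or trivial
      gene_path <- igraph::V(pg$graph)$name[vp]
      k <- k + 1L
      rows[[k]] <- data.frame(source = s,
                              target = gene_path[length(gene_path)],
                              cost = path_cost(gene_path, pg$what),
                              stringsAsFactors = FALSE)
      paths[[k]] <- gene_path
    }
  }
  if (!k) stop("no reachable terminal pair")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, paths = paths, terminals = terms,
            class = c("CandidatePaths", "data.frame"))
}

#' Cost of a concrete node path under normalised weights
#' @noRd
path_cost <- function(gene_path, what) {
  u <- gene_path[-length(gene_path)]
  v <- gene_path[-1]
  sum(1 / sqrt(what[u] * what[v]))
}

#' Permutation significance of candidate paths
#'
#' The null shuffles node weights uniformly over the network nodes,
#' rebuilds the edge costs and recomputes the minimum-cost distance for the
#' same terminal pairs; topology is untouched, so the test asks whether the
#' observed placement of weight makes the paths cheaper than chance.  The
#' plus-one estimator `p = (1 + #{C_perm <= C_obs}) / (1 + n_perm)` never
#' returns 0; its minimum is `1/(n_perm + 1)`.
#'
#' @param pg the [build_path_graph()] the paths came from.
#' @param paths a [candidate_paths()] result.
#' @param n_perm number of permutations (default 200).
#' @param seed integer seed; required, this is a reproducibility contract.
#' @return `paths` with a `p_value` column appended.
#' @export
permutation_significance <- function(pg, paths, n_perm = 200, seed) {
  stopifnot(inherits(pg, "WeightedPathGraph"),
            inherits(paths, "CandidatePaths"), n_perm >= 1)
  if (missing(seed) || is.null(seed))
    stop("a seed is required for the permutation null")
  terms <- attr(paths, "terminals")
  src <- match(paths$source, terms)
  dst <- match(paths$target, terms)
  obs <- paths$cost
  hits <- integer(nrow(paths))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      wperm <- stats::setNames(sample(pg$what), pg$nodes)
      d <- igraph::distances(pg$graph, v = terms, to = terms,
                             mode = "out",
                             weights = edge_costs(pg$graph, wperm))
      perm_cost <- d[cbind(src, dst)]
      hits <- hits + (perm_cost <= obs)
    }
  })
  paths$p_value <- (1 + hits) / (1 + n_perm)
  paths
}

#' Build a TopNet from significant paths
#'
#' Pair p-values are BH-adjusted; the TopNet is the union of the directed
#' edges of every path with adjusted p <= `alpha`.  An empty TopNet (no
#' significant path) is a valid outcome and is returned with a warning.
#'
#' @param paths a [permutation_significance()] result (has `p_value`).
#' @param alpha significance level after BH adjustment (default 0.05).
#' @return A `TopNet`: list with `nodes`, `edges` (data frame `from`,
#'   `to`), `pairs` (the path table with `adj_p`), `graph` (directed
#'   igraph).
#' @export
build_topnet <- function(paths, alpha = 0.05) {
  stopifnot(inherits(paths, "CandidatePaths"), alpha > 0, alpha < 1)
  if (is.null(paths$p_value))
    stop("paths carry no p-values; run permutation_significance() first")
  paths$adj_p <- stats::p.adjust(paths$p_value, method = "BH")
  sig <- which(paths$adj_p <= alpha)
  plist <- attr(paths, "paths")
  if (!length(sig)) {
    warning("no significant path; TopNet is empty")
    return(structure(list(nodes = character(0),
                          edges = data.frame(from = character(0),
                                             to = character(0)),
                          pairs = as.data.frame(paths),
                          graph = igraph::make_empty_graph(directed = TRUE)),
                     class = "TopNet"))
  }
  edges <- do.call(rbind, lapply(plist[sig], function(p)
    data.frame(from = p[-length(p)], to = p[-1], stringsAsFactors = FALSE)))
  edges <- unique(edges)
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = nodes)
  structure(list(nodes = nodes, edges = edges,
                 pairs = as.data.frame(paths), graph = g),
            class = "TopNet")
}

#' @exportS3Method base::print
print.TopNet <- function(x, ...) {
  cat(sprintf("TopNet: %d nodes, %d edges (%d candidate pairs)\n",
              length(x$nodes), nrow(x$edges), nrow(x$pairs)))
  invisible(x)
}

#' Ripple centrality of TopNet genes
#'
#' `r(v) = sqrt(R_out(v) * R_in(v)) / (n - 1)` where `R_out`/`R_in` count
#' the TopNet nodes reachable from / reaching `v` (excluding `v`) and `n`
#' is the TopNet node count.  A node must both broadcast and receive to
#' score: sources and sinks get 0, a node on every path gets close to 1.
#'
#' @param topnet a [build_topnet()] result.
#' @return Named numeric vector, gene -> centrality in `[0, 1]`; empty
#'   TopNets (n <= 1) give an empty / all-zero vector.
#' @export
ripple_centrality <- function(topnet) {
  stopifnot(inherits(topnet, "TopNet"))
  n <- length(topnet$nodes)
  if (n == 0) return(stats::setNames(numeric(0), character(0)))
  if (n == 1) return(stats::setNames(0, topnet$nodes))
  d <- igraph::distances(topnet$graph, mode = "out", weights = NA)
  reach_out <- rowSums(is.finite(d)) - 1
  reach_in <- colSums(is.finite(d)) - 1
  r <- sqrt(reach_out * reach_in) / (n - 1)
  stats::setNames(as.numeric(r[topnet$nodes]), topnet$nodes)
}

#' Per-sample TopNet pipeline
#'
#' Weights -> path graph -> candidate paths -> permutation null -> TopNet
#' with ripple centralities, for one case sample.
#'
#' @param expr an [expression_matrix()].
#' @param network an [interaction_network()].
#' @param sample case sample ID.
#' @param mode `"activated"` or `"repressed"` weight gate.
#' @param terminal_fraction fraction of nodes used as path terminals.
#' @param n_perm permutations for the null (default 200).
#' @param alpha BH-adjusted significance level.
#' @param span loess span for the expected-|log2FC| trend.
#' @param eps weight floor.
#' @param seed integer seed.
#' @return The `TopNet` with an added `centrality` element (named vector)
#'   and `sample` element.
#' @export
pathext_sample <- function(expr, network, sample, mode = "activated",
                           terminal_fraction = 0.05, n_perm = 200,
                           alpha = 0.05, span = 0.75, eps = 1e-4, seed) {
  nw <- sample_node_weights(expr, sample, mode = mode, span = span,
                            eps = eps)
  pg <- build_path_graph(network, nw)
  cp <- candidate_paths(pg, terminal_fraction)
  cp <- permutation_significance(pg, cp, n_perm = n_perm, seed = seed)
  tn <- build_topnet(cp, alpha = alpha)
  tn$centrality <- ripple_centrality(tn)
  tn$sample <- sample
  tn
}
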