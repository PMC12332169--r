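# Independent oracles: brute-force or closed-form computations the
# implementation under test never shares code with.

# Minimum cost over all simple s->t paths by exhaustive recursion.
# adj: named list node -> character vector of neighbours (directed arcs).
enum_min_path_cost <- function(adj, what, s, t) {
  best <- Inf
  recurse <- function(node, visited, cost) {
    if (cost >= best) return()
    if (node == t) { best <<- cost; return() }
    for (nb in adj[[node]]) {
      if (nb %in% visited) next
      recurse(nb, c(visited, nb),
              cost + 1 / sqrt(what[[node]] * what[[nb]]))
    }
  }
  recurse(s, s, 0)
  best
}

# Undirected edge list -> symmetric adjacency list.
edges_to_adj <- function(edges, nodes) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$source[i]; b <- edges$target[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# Upper-tail hypergeometric P(X >= a) by full enumeration of all C(N, n)
# draws of the query from a universe with K marked elements.
hyper_upper_enum <- function(N, K, n, a) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  mean(apply(draws, 2, function(d) sum(d %in% marked) >= a))
}

# AUROC by direct pair counting.
auroc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (x in pos) for (y in neg)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(pos) * length(neg))
}

# Delete-one jackknife variance of the AUROC.
jackknife_auroc_var <- function(scores, labels) {
  n <- length(scores)
  th <- vapply(seq_len(n), function(i) auroc(scores[-i], labels[-i]),
               numeric(1))
  (n - 1) / n * sum((th - mean(th))^2)
}

# Reachability counts by boolean transitive closure (matrix powers).
closure_reach <- function(edges, nodes) {
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  A[cbind(edges$from, edges$to)] <- TRUE
  R <- A
  repeat {
    R2 <- R | (R %*% A > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  list(out = rowSums(R & !diag(n)), inn = colSums(R & !diag(n)))
}

# Small random connected-ish undirected test network.
random_test_network <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  genes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- t(utils::combn(genes, 2))
  pick <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  interaction_network(data.frame(source = pairs[pick, 1],
                                 target = pairs[pick, 2],
                                 confidence = 1))
}
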