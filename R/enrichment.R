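# Over-representation and gene-list overlap statistics.
#
# Both tests share the same 2x2 table of a query list against a reference
# set inside a background universe of N genes:
#       a = |query  &  set|     b = |query \ set|
#       c = |set \ query|       d = N - a - b - c
# ORA uses the upper-tail hypergeometric p; list-vs-list overlap reports
# the sample odds ratio (a*d)/(b*c) and a two-sided Fisher exact p.  The
# default background of 20,000 genes is the conventional protein-coding
# universe.

#' One 2x2 overlap row
#' @noRd
overlap_row <- function(name, a, n_query, n_set, N) {
  b <- n_query - a
  cc <- n_set - a
  d <- N - a - b - cc
  or <- if (a == 0) 0
        else if (b == 0 || cc == 0) Inf
        else (a * d) / (b * cc)
  data.frame(name = name, a = a, b = b, c = cc, d = d,
             odds_ratio = or, stringsAsFactors = FALSE)
}

#' Two-sided Fisher exact p by the point-probability rule
#'
#' Sums the hypergeometric probabilities of all tables (given the margins)
#' whose probability does not exceed that of the observed table, with the
#' usual (1 + 1e-7) tolerance for ties.
#' @noRd
fisher_two_sided_p <- function(a, n_query, n_set, N) {
  support <- max(0, n_query + n_set - N):min(n_query, n_set)
  dens <- stats::dhyper(support, n_set, N - n_set, n_query)
  sum(dens[dens <= dens[support == a] * (1 + 1e-7)])
}

#' Hypergeometric over-representation analysis
#'
#' Tests a query gene list against every set of a collection within a
#' background universe.  Set members are first intersected with the
#' background; only sets whose filtered size lies in
#' `[min_size, max_size]` are tested.  The p-value is the upper tail
#' `P(X >= a)` of the hypergeometric; BH adjustment is across the tested
#' sets.
#'
#' @param query character vector of query genes (must lie in `background`;
#'   outsiders are dropped with a warning).
#' @param collection a [gene_set_collection()].
#' @param background character vector: the gene universe.
#' @param min_size,max_size inclusive bounds on filtered set size
#'   (defaults 10 and 500).
#' @return Data frame (`OverlapResult` rows): `name`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p_value`, `adj_p`, `set_size`, ordered by `p_value`.
#' @export
hypergeom_ora <- function(query, collection, background,
                          min_size = 10, max_size = 500) {
  if (!length(background)) stop("empty background universe")
  background <- unique(background)
  query <- unique(query)
  outside <- setdiff(query, background)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the background dropped")
    query <- intersect(query, background)
  }
  N <- length(background)
  rows <- list()
  for (nm in names(collection)) {
    members <- intersect(collection[[nm]], background)
    K <- length(members)
    if (K < min_size || K > max_size) next
    a <- length(intersect(query, members))
    row <- overlap_row(nm, a, length(query), K, N)
    row$p_value <- stats::phyper(a - 1, K, N - K, length(query),
                                 lower.tail = FALSE)
    row$set_size <- K
    rows[[nm]] <- row
  }
  if (!length(rows))
    return(data.frame(name = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0),
                      odds_ratio = numeric(0), p_value = numeric(0),
                      adj_p = numeric(0), set_size = integer(0)))
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$name), ]
  rownames(out) <- NULL
  out
}

#' Fisher's exact overlap of two gene lists
#'
#' Reports the sample odds ratio `(a*d)/(b*c)` (the convention behind
#' benchmark-overlap tables: OR > 1 means enrichment) and a two-sided
#' Fisher exact p-value, computed by hypergeometric enumeration with the
#' point-probability rule.
#'
#' @param query,reference character vectors of genes.
#' @param background_size size N of the gene universe (default 20000, the
#'   conventional protein-coding count; must be at least
#'   `|query union reference|`).
#' @return One-row data frame: `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `p_value`.
#' @export
fisher_overlap <- function(query, reference, background_size = 20000) {
  query <- unique(query); reference <- unique(reference)
  if (background_size < length(union(query, reference)))
    stop("background_size smaller than |query U reference|")
  a <- length(intersect(query, reference))
  out <- overlap_row("overlap", a, length(query), length(reference),
                     background_size)
  out$p_value <- fisher_two_sided_p(a, length(query), length(reference),
                                    background_size)
  out$name <- NULL
  out
}

#' Fisher overlap from counts alone
#'
#' Same statistic as [fisher_overlap()] when only the counts are known:
#' `a` query genes of `n_query` fall in a reference list of size `n_ref`
#' within a universe of `background_size` genes.
#'
#' @param a overlap count.
#' @param n_query query-list size.
#' @param n_ref reference-list size.
#' @param background_size universe size N.
#' @return One-row data frame as in [fisher_overlap()].
#' @export
fisher_overlap_counts <- function(a, n_query, n_ref,
                                  background_size = 20000) {
  stopifnot(a >= 0, a <= n_query, a <= n_ref,
            background_size >= n_query + n_ref - a)
  out <- overlap_row("overlap", a, n_query, n_ref, background_size)
  out$p_value <- fisher_two_sided_p(a, n_query, n_ref, background_size)
  out$name <- NULL
  out
}

#' Greedy redundancy reduction of enrichment results
#'
#' Walks the results by ascending adjusted p-value and keeps a term only
#' if its member-set Jaccard similarity with every already-kept term is at
#' most `cutoff`.  This is a membership-based stand-in for
#' ontology-graph semantic-similarity pruning at the same cutoff.
#'
#' @param results data frame from [hypergeom_ora()] (needs `name`,
#'   `adj_p`).
#' @param member_map named list: term -> member genes (e.g. the
#'   collection).
#' @param cutoff Jaccard similarity above which a term is redundant
#'   (default 0.8).
#' @return The kept subset of `results`, ascending `adj_p`.
#' @export
reduce_redundancy <- function(results, member_map, cutoff = 0.8) {
  stopifnot(cutoff > 0, cutoff <= 1)
  if (!nrow(results)) return(results)
  ord <- order(results$adj_p, results$name)
  results <- results[ord, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(results))) {
    mem_i <- unique(member_map[[results$name[i]]])
    redundant <- FALSE
    for (j in kept) {
      mem_j <- unique(member_map[[results$name[j]]])
      jac <- length(intersect(mem_i, mem_j)) / length(union(mem_i, mem_j))
      if (jac > cutoff) { redundant <- TRUE; break }
    }
    if (!redundant) kept <- c(kept, i)
  }
  out <- results[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}
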