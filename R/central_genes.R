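# Cohort-level central genes: per-sample top-k by ripple centrality,
# aggregated by frequency across the samples with a non-empty TopNet.

#' Top-k genes of one sample's TopNet by ripple centrality
#'
#' @param topnet a `TopNet` carrying a `centrality` vector (from
#'   [pathext_sample()]; otherwise computed here).
#' @param k list length (default 100); ties broken by gene ID; fewer than
#'   `k` nodes returns all of them.
#' @return Ordered character vector; empty for an empty TopNet (the sample
#'   then counts as non-significant).
#' @export
top_k_per_sample <- function(topnet, k = 100) {
  stopifnot(inherits(topnet, "TopNet"), k >= 1)
  r <- topnet$centrality
  if (is.null(r)) r <- ripple_centrality(topnet)
  if (!length(r)) return(character(0))
  ord <- order(-r, names(r))
  utils::head(names(r)[ord], k)
}

#' Frequency-ranked central genes across samples
#'
#' A sample is "significant" when its per-sample list is non-empty; the
#' number of significant samples is the denominator of `freq_fraction`.
#' Genes are ranked by frequency (count of per-sample lists containing
#' them), ties by mean centrality then gene ID, and the top `k_final` are
#' returned.
#'
#' @param per_sample_lists named list (sample -> character vector) of
#'   per-sample top-k genes.
#' @param k_final final list length (default 100).
#' @param centralities optional named list (sample -> named centrality
#'   vector) used for the mean-centrality tie-break; genes missing from a
#'   sample contribute nothing.
#' @return A `CentralGeneTable` data frame: `gene`, `frequency`,
#'   `freq_fraction`, `mean_centrality`, with attribute `n_significant`.
#' @export
frequency_rank <- function(per_sample_lists, k_final = 100,
                           centralities = NULL) {
  stopifnot(k_final >= 1)
  nonempty <- per_sample_lists[lengths(per_sample_lists) > 0]
  n_sig <- length(nonempty)
  if (!n_sig) stop("no significantly altered samples")
  freq <- table(unlist(lapply(nonempty, unique)))
  genes <- names(freq)
  mean_c <- rep(NA_real_, length(genes))
  if (!is.null(centralities)) {
    all_c <- unlist(unname(lapply(centralities, function(v) v[names(v) %in% genes])))
    sums <- tapply(all_c, names(all_c), sum)
    cnts <- tapply(all_c, names(all_c), length)
    mean_c <- as.numeric((sums / cnts)[genes])
    mean_c[is.na(mean_c)] <- 0
  } else mean_c <- rep(0, length(genes))
  out <- data.frame(gene = genes, frequency = as.integer(freq),
                    freq_fraction = as.integer(freq) / n_sig,
                    mean_centrality = mean_c, stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, -out$mean_centrality, out$gene), ,
             drop = FALSE]
  out <- utils::head(out, k_final)
  rownames(out) <- NULL
  attr(out, "n_significant") <- n_sig
  class(out) <- c("CentralGeneTable", "data.frame")
  out
}

#' Cohort-level central genes from expression + network
#'
#' Runs [pathext_sample()] for every case sample, takes the per-sample
#' top-`k` genes by ripple centrality, and frequency-ranks them into the
#' final central-gene table.  Per-sample permutation seeds are derived
#' deterministically from `seed`.
#'
#' @inheritParams pathext_sample
#' @param k per-sample list length (default 100).
#' @param k_final final central-gene count (default 100).
#' @param verbose print one line per sample.
#' @return List with `central` (the `CentralGeneTable`), `per_sample`
#'   (named list of per-sample gene lists) and `topnets` (named list of
#'   `TopNet`s).
#' @export
central_genes <- function(expr, network, mode = "activated", k = 100,
                          k_final = 100, terminal_fraction = 0.05,
                          n_perm = 200, alpha = 0.05, span = 0.75,
                          eps = 1e-4, seed = 1, verbose = FALSE) {
  cases <- group_samples(expr, "case")
  topnets <- list(); lists <- list(); cents <- list()
  for (i in seq_along(cases)) {
    s <- cases[i]
    tn <- suppressWarnings(pathext_sample(
      expr, network, s, mode = mode, terminal_fraction = terminal_fraction,
      n_perm = n_perm, alpha = alpha, span = span, eps = eps,
      seed = (seed * 1009L + i) %% .Machine$integer.max))
    topnets[[s]] <- tn
    lists[[s]] <- top_k_per_sample(tn, k)
    cents[[s]] <- tn$centrality
    if (verbose)
      message(sprintf("%s: TopNet %d nodes, top-%d kept", s,
                      length(tn$nodes), length(lists[[s]])))
  }
  list(central = frequency_rank(lists, k_final, cents),
       per_sample = lists, topnets = topnets)
}
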