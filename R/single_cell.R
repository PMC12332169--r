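# Cell-type specificity of gene sets on a cell x gene matrix: per-gene
# one-way ANOVA across cell types, z-scoring of type means, and the
# log2 observed/expected fraction of set genes "expressed" per type.

#' Per-gene cell-type statistics
#'
#' Mean and variance of every gene within each cell type plus a classic
#' one-way ANOVA across types (`F = MS_between / MS_within` on
#' `(k - 1, n - k)` df).  Genes with zero total variance get `F = 0`,
#' `p = 1`.
#'
#' @param mat numeric cells x genes matrix (cells in rows).
#' @param labels character vector (or named vector keyed by rowname) of
#'   cell types, length `nrow(mat)`; >= 2 types with >= 2 cells each.
#' @return A `CellTypeProfile`: list with `means` and `vars`
#'   (types x genes matrices), `anova` (data frame `gene`, `F`,
#'   `p_value`), `n_per_type`.
#' @export
celltype_stats <- function(mat, labels) {
  if (!is.null(names(labels)) && !is.null(rownames(mat)))
    labels <- labels[rownames(mat)]
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(mat))
  counts <- table(labels)
  if (length(counts) < 2 || any(counts < 2))
    stop("need >= 2 cell types with >= 2 cells each")
  types <- names(counts)
  k <- length(types); n <- nrow(mat)
  means <- do.call(rbind, lapply(types, function(ty)
    colMeans(mat[labels == ty, , drop = FALSE])))
  vars <- do.call(rbind, lapply(types, function(ty)
    apply(mat[labels == ty, , drop = FALSE], 2, stats::var)))
  rownames(means) <- rownames(vars) <- types
  grand <- colMeans(mat)
  n_t <- as.numeric(counts[types])
  ssb <- colSums(n_t * (sweep(means, 2, grand))^2)
  ssw <- colSums((n_t - 1) * vars)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  f <- ifelse(msw > 0, msb / msw, 0)
  p <- ifelse(msw > 0, stats::pf(f, k - 1, n - k, lower.tail = FALSE), 1)
  zero_tot <- (ssb + ssw) < .Machine$double.eps
  f[zero_tot] <- 0; p[zero_tot] <- 1
  structure(list(means = means, vars = vars,
                 anova = data.frame(gene = colnames(mat), F = f,
                                    p_value = p, row.names = NULL,
                                    stringsAsFactors = FALSE),
                 n_per_type = counts),
            class = "CellTypeProfile")
}

#' Z-score type means across cell types
#'
#' Per gene: `(mean_t - row mean) / row sample sd`, giving each gene mean
#' 0 and sample sd 1 across types; genes with zero sd across types get an
#' all-zero row.
#'
#' @param type_means types x genes matrix (e.g. `celltype_stats()$means`).
#' @return Matrix of the same shape.
#' @export
zscore_across_types <- function(type_means) {
  stopifnot(nrow(type_means) >= 2)
  mu <- colMeans(type_means)
  sdv <- apply(type_means, 2, stats::sd)
  z <- sweep(sweep(type_means, 2, mu), 2, ifelse(sdv > 0, sdv, 1), "/")
  z[, sdv == 0] <- 0
  z
}

#' Observed vs expected expressed fraction of a gene set per cell type
#'
#' A gene counts as "expressed" in a type when its z-scored type mean
#' exceeds `expressed_threshold` (default 0: above its own cross-type
#' average).  Per type, `obs_frac` is the fraction of set genes expressed,
#' `exp_frac` the fraction of all matrix genes expressed, and
#' `log2_ratio = log2((obs + delta) / (exp + delta))` with a small
#' `delta` guarding against log of zero.
#'
#' @param geneset character vector; must intersect the matrix genes.
#' @param z types x genes z-score matrix from [zscore_across_types()].
#' @param expressed_threshold z cutoff for "expressed" (default 0).
#' @param delta smoothing constant (default 1e-6).
#' @param expected_over `"all"` genes (default) or `"set"`-tested genes
#'   only -- i.e. whether `exp_frac` uses the whole matrix universe.
#' @return Data frame: `cell_type`, `obs_frac`, `exp_frac`, `log2_ratio`.
#' @export
obs_exp_fraction <- function(geneset, z, expressed_threshold = 0,
                             delta = 1e-6, expected_over = c("all", "set")) {
  expected_over <- match.arg(expected_over)
  geneset <- intersect(unique(geneset), colnames(z))
  if (!length(geneset)) stop("gene set does not intersect the matrix genes")
  expressed <- z > expressed_threshold
  obs <- rowMeans(expressed[, geneset, drop = FALSE])
  expd <- if (expected_over == "all") rowMeans(expressed)
          else rowMeans(expressed[, geneset, drop = FALSE])
  data.frame(cell_type = rownames(z), obs_frac = as.numeric(obs),
             exp_frac = as.numeric(expd),
             log2_ratio = log2((obs + delta) / (expd + delta)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full single-cell overlay for a gene set
#'
#' @inheritParams celltype_stats
#' @inheritParams obs_exp_fraction
#' @return List with `profile` (a `CellTypeProfile`), `z` and `overlay`
#'   (the [obs_exp_fraction()] table).
#' @export
sc_overlay <- function(mat, labels, geneset, expressed_threshold = 0) {
  prof <- celltype_stats(mat, labels)
  z <- zscore_across_types(prof$means)
  list(profile = prof, z = z,
       overlay = obs_exp_fraction(geneset, z, expressed_threshold))
}
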