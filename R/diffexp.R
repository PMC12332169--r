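# Cohort-level differential expression.  Serves as the comparison baseline
# for the network pipeline, not the headline method: a Welch t-test or a
# documented moderated-t stand-in (gene variances shrunk toward the median
# variance with prior df d0 = 4), with BH step-up FDR across all genes.

#' Two-group differential expression
#'
#' `log2FC` is always case mean minus control mean in log2 units.
#' `method = "welch"` is the unequal-variance two-sample t-test.
#' `method = "moderated"` shrinks each gene's pooled variance toward the
#' median gene variance with prior degrees of freedom `d0 = 4` and uses a
#' pooled-design t statistic on `d0 + df` degrees of freedom; it is a
#' lightweight stand-in for empirical-Bayes moderation, stabilising
#' low-replicate variance estimates.
#'
#' @param expr an [expression_matrix()] (>= 2 samples per group).
#' @param method `"moderated"` (default) or `"welch"`.
#' @param d0 prior degrees of freedom for the moderated variance.
#' @return A `DEGTable` data frame: `gene`, `log2FC`, `t_stat`, `p_value`,
#'   `fdr` (Benjamini-Hochberg), ordered as the input genes.
#' @export
differential_expression <- function(expr, method = c("moderated", "welch"),
                                    d0 = 4) {
  method <- match.arg(method)
  stopifnot(inherits(expr, "ExpressionMatrix"))
  case <- expr$values[, group_samples(expr, "case"), drop = FALSE]
  ctrl <- expr$values[, group_samples(expr, "control"), drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per group")
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  v1 <- apply(case, 1, stats::var); v2 <- apply(ctrl, 1, stats::var)
  lfc <- m1 - m2

  if (method == "welch") {
    se2 <- v1 / n1 + v2 / n2
    tt <- ifelse(se2 > 0, lfc / sqrt(se2), 0)
    df <- ifelse(se2 > 0,
                 se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
                 1)
    p <- 2 * stats::pt(-abs(tt), df)
    zero <- se2 == 0
    if (any(zero)) {
      warning(sum(zero), " gene(s) with zero within-group variance; ",
              "p set to 0 when means differ, 1 otherwise")
      p[zero] <- ifelse(lfc[zero] != 0, 0, 1)
      tt[zero] <- ifelse(lfc[zero] != 0, sign(lfc[zero]) * Inf, 0)
    }
  } else {
    df <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df        # pooled per gene
    s2_0 <- stats::median(s2)                          # common prior
    s2_post <- (d0 * s2_0 + df * s2) / (d0 + df)
    se <- sqrt(s2_post * (1 / n1 + 1 / n2))
    tt <- ifelse(se > 0, lfc / se, ifelse(lfc != 0, Inf, 0) * sign(lfc + (lfc == 0)))
    p <- 2 * stats::pt(-abs(tt), d0 + df)
    p[se == 0] <- ifelse(lfc[se == 0] != 0, 0, 1)
  }

  data.frame(gene = rownames(expr$values), log2FC = lfc, t_stat = tt,
             p_value = p, fdr = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select the top differentially expressed genes
#'
#' Filters to `fdr <= fdr_max`, sorts by signed `log2FC` descending
#' (upregulated first; use `by_abs = TRUE` to rank by magnitude), breaks
#' ties by smaller p-value then lexicographic gene ID, and returns the
#' first `k`.
#'
#' @param table a `DEGTable` from [differential_expression()].
#' @param k number of genes to keep (default 100).
#' @param fdr_max FDR cutoff (default 0.05).
#' @param by_abs rank by `|log2FC|` instead of signed value.
#' @return Ordered character vector of gene IDs; fewer than `k` survivors
#'   returns all of them with a warning.
#' @export
select_top_degs <- function(table, k = 100, fdr_max = 0.05, by_abs = FALSE) {
  stopifnot(k >= 1)
  keep <- table[table$fdr <= fdr_max, , drop = FALSE]
  if (nrow(keep) == 0) {
    warning("no genes at FDR <= ", fdr_max)
    return(character(0))
  }
  key <- if (by_abs) abs(keep$log2FC) else keep$log2FC
  keep <- keep[order(-key, keep$p_value, keep$gene), , drop = FALSE]
  if (nrow(keep) < k)
    warning("only ", nrow(keep), " genes at FDR <= ", fdr_max,
            " (requested ", k, ")")
  utils::head(keep$gene, k)
}
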