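# Per-sample node weights: the positive residual of the observed absolute
# log2 fold change over a loess-expected trend in control expression.
# Raw |log2FC| overemphasises noisy low-expression genes; regressing
# |log2FC| on control expression and keeping only the excess corrects the
# expression-dependent variance before path scoring.

#' Per-sample signed log2 fold change against the control reference
#'
#' @param expr an [expression_matrix()] (log2 units).
#' @param sample a case sample ID.
#' @param reference control summary per gene: `"median"` (robust default)
#'   or `"mean"`.
#' @return Named numeric vector, gene -> signed log2FC.
#' @export
per_sample_logfc <- function(expr, sample, reference = c("median", "mean")) {
  reference <- match.arg(reference)
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (!sample %in% group_samples(expr, "case"))
    stop("'", sample, "' is not a case sample")
  ctrl <- expr$values[, group_samples(expr, "control"), drop = FALSE]
  if (ncol(ctrl) < 2) stop("need >= 2 control samples")
  ref <- if (reference == "median") apply(ctrl, 1, stats::median)
         else rowMeans(ctrl)
  expr$values[, sample] - ref
}

#' Control reference expression per gene
#'
#' The x-axis of the loess fit: the same control summary used for the fold
#' change.
#'
#' @inheritParams per_sample_logfc
#' @return Named numeric vector, gene -> control reference (log2).
#' @export
control_reference <- function(expr, reference = c("median", "mean")) {
  reference <- match.arg(reference)
  ctrl <- expr$values[, group_samples(expr, "control"), drop = FALSE]
  if (reference == "median") apply(ctrl, 1, stats::median) else rowMeans(ctrl)
}

#' Loess-expected absolute log2 fold change
#'
#' Local linear regression (tricube weights, `span` fraction of points per
#' local fit) of `|log2FC|` on control reference expression, evaluated at
#' every gene and clipped at zero.  Degenerate x (all control references
#' identical) falls back to the global mean of `|log2FC|` with a warning.
#'
#' @param abs_logfc named numeric vector of `|log2FC|` values.
#' @param control_ref_expr named numeric vector of control reference
#'   expression, same genes.
#' @param span loess span in `(0, 1]` (default 0.75).
#' @return Named numeric vector, gene -> expected `|log2FC|` (>= 0).
#' @export
loess_expected <- function(abs_logfc, control_ref_expr, span = 0.75) {
  stopifnot(span > 0, span <= 1)
  genes <- names(abs_logfc)
  if (is.null(genes) || !identical(sort(genes), sort(names(control_ref_expr))))
    stop("abs_logfc and control_ref_expr must cover the same genes")
  x <- control_ref_expr[genes]
  if (length(genes) < 30) stop("need >= 30 genes for a stable loess fit")
  if (diff(range(x)) < .Machine$double.eps^0.5) {
    warning("control reference expression is constant; ",
            "using the global mean |log2FC|")
    return(stats::setNames(rep(mean(abs_logfc), length(genes)), genes))
  }
  fit <- stats::loess(y ~ x, data = data.frame(x = x, y = abs_logfc),
                      span = span, degree = 1, family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  stats::setNames(pmax(stats::predict(fit, newdata = data.frame(x = x)), 0),
                  genes)
}

#' Residual node weights for one sample
#'
#' In `"activated"` mode a gene with positive log2FC gets
#' `max(|log2FC| - expected, 0) + eps`; all other genes get the floor
#' `eps`.  `"repressed"` mirrors the rule for negative log2FC.  The floor
#' keeps every weight strictly positive, which downstream path costs
#' require.
#'
#' @param signed_logfc named numeric vector from [per_sample_logfc()].
#' @param expected named numeric vector from [loess_expected()] on the
#'   same genes.
#' @param mode `"activated"` (default) or `"repressed"`.
#' @param eps strictly positive weight floor (default 1e-4).
#' @return A `NodeWeightVector`: list with `weights`, `signed_logfc`,
#'   `expected` (aligned named vectors), `mode` and `eps`.
#' @export
residual_weights <- function(signed_logfc, expected,
                             mode = c("activated", "repressed"),
                             eps = 1e-4) {
  mode <- match.arg(mode)
  if (eps <= 0) stop("eps must be > 0 (zero weights break path costs)")
  genes <- names(signed_logfc)
  if (is.null(genes) || !identical(sort(genes), sort(names(expected))))
    stop("signed_logfc and expected must cover the same genes")
  expected <- expected[genes]
  excess <- pmax(abs(signed_logfc) - expected, 0)
  gate <- if (mode == "activated") signed_logfc > 0 else signed_logfc < 0
  w <- ifelse(gate, excess + eps, eps)
  structure(list(weights = stats::setNames(w, genes),
                 signed_logfc = signed_logfc, expected = expected,
                 mode = mode, eps = eps),
            class = "NodeWeightVector")
}

#' @exportS3Method base::print
print.NodeWeightVector <- function(x, ...) {
  cat(sprintf("NodeWeightVector (%s): %d genes, %d above floor\n",
              x$mode, length(x$weights), sum(x$weights > x$eps)))
  invisible(x)
}

#' Node weights for one case sample, end to end
#'
#' Convenience wrapper: per-sample log2FC, loess-expected trend, residual
#' weights.
#'
#' @inheritParams per_sample_logfc
#' @inheritParams residual_weights
#' @param span loess span.
#' @return A `NodeWeightVector`.
#' @export
sample_node_weights <- function(expr, sample, mode = "activated",
                                reference = "median", span = 0.75,
                                eps = 1e-4) {
  lfc <- per_sample_logfc(expr, sample, reference)
  expc <- loess_expected(abs(lfc), control_reference(expr, reference), span)
  residual_weights(lfc, expc, mode, eps)
}
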