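# Classifier evaluation machinery: stratified k-fold cross-validation over
# a small set of learners, threshold-free metrics (AUROC by the
# Mann-Whitney identity, AUPRC as average precision), F1 at 0.5,
# percentile-bootstrap confidence intervals, and the fast DeLong test for
# comparing correlated AUROCs via placement values.
#
# The tree learners are decision-stump ensembles (bagged, extremely
# randomised, AdaBoost, gradient-boosted); "svm" is an L2-regularised
# linear (logistic) model fit with glmnet standing in for a linear
# max-margin classifier.  All are contract-level: the evaluation
# statistics, not the learners, are the point.

#' AUROC by the Mann-Whitney identity
#'
#' Probability that a random positive outscores a random negative, ties
#' counting one half.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 or logical labels (1/TRUE = positive); both classes
#'   must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-interpolated average precision over descending score thresholds;
#' tied scores are grouped.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1)
  if (n1 == 0 || n1 == length(labels)) stop("both classes must be present")
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- tapply(cumsum(y), grp, max)
  np <- tapply(seq_along(y), grp, max)
  prec <- tp / np
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' F1 score at a probability threshold
#'
#' @inheritParams auroc
#' @param threshold score cutoff for calling a positive (default 0.5).
#' @return F1 in `[0, 1]` (0 when no positives are called or present).
#' @export
f1_score <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(as.logical(labels))
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & labels == 1)
  denom <- 2 * tp + sum(pred == 1 & labels == 0) + sum(pred == 0 & labels == 1)
  if (denom == 0) return(0)
  2 * tp / denom
}

#' Percentile bootstrap confidence interval for a score metric
#'
#' Resamples (score, label) pairs with replacement; resamples containing a
#' single class are discarded and redrawn.
#'
#' @inheritParams auroc
#' @param metric function `(scores, labels) -> number` (default [auroc()]).
#' @param n_boot bootstrap replicates (>= 100; default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed.
#' @return Named vector `c(lo, hi)`.
#' @export
bootstrap_ci <- function(scores, labels, metric = auroc, n_boot = 1000,
                         conf = 0.95, seed = 1) {
  stopifnot(n_boot >= 100)
  labels <- as.integer(as.logical(labels))
  n <- length(scores)
  with_seed(seed, {
    vals <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2) break
      }
      vals[b] <- metric(scores[idx], labels[idx])
    }
    q <- stats::quantile(vals, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                         names = FALSE, type = 7)
    c(lo = q[1], hi = q[2])
  })
}

#' Placement values for the fast DeLong machinery
#' @noRd
placements <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  all_r <- rank(c(x, y))
  rx <- rank(x); ry <- rank(y)
  v10 <- (all_r[seq_len(m)] - rx) / n          # per-positive placement
  v01 <- 1 - (all_r[m + seq_len(n)] - ry) / m  # per-negative placement
  list(v10 = v10, v01 = v01, theta = mean(v10))
}

#' DeLong variance of a single AUROC
#'
#' @inheritParams auroc
#' @return Variance estimate of the empirical AUROC.
#' @export
delong_variance <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  p <- placements(scores, labels)
  stats::var(p$v10) / length(p$v10) + stats::var(p$v01) / length(p$v01)
}

#' DeLong's test for two correlated AUROCs
#'
#' Both score vectors must be computed on the same samples (paired
#' design).  Uses placement values and their empirical covariance; the
#' statistic is `z = (theta_a - theta_b) / sqrt(var)` with a two-sided
#' normal p-value.  Identical scores (zero variance of the difference)
#' give `z = 0`, `p = 1`.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels 0/1 labels shared by both.
#' @return List with `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  stopifnot(length(scores_a) == length(scores_b))
  labels <- as.integer(as.logical(labels))
  pa <- placements(scores_a, labels)
  pb <- placements(scores_b, labels)
  m <- length(pa$v10); n <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$theta - pb$theta
  if (v <= .Machine$double.eps) {
    z <- 0; p <- 1
  } else {
    z <- d / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = pa$theta, auc_b = pb$theta, z = z, p_value = p)
}

## ---- decision-stump learners ------------------------------------------

#' Best weighted classification stump over a feature subset
#' @noRd
fit_class_stump <- function(X, y, w, features) {
  best <- list(err = Inf)
  for (j in features) {
    x <- X[, j]
    ord <- order(x)
    xo <- x[ord]; yo <- y[ord]; wo <- w[ord]
    # error of rule "predict +1 when x > thr" as thr sweeps the sorted values
    wpos <- sum(w[y == 1]); # total positive weight
    cum_pos <- cumsum(wo * (yo == 1))   # positives at or below i
    cum_neg <- cumsum(wo * (yo == 0))
    tot_neg <- sum(wo * (yo == 0))
    # threshold after position i: err = pos<=i misclassified + neg>i misclassified
    err_gt <- cum_pos + (tot_neg - cum_neg)
    err_le <- (wpos - cum_pos) + cum_neg  # rule "predict +1 when x <= thr"
    cand <- which(diff(xo) > 0)
    if (!length(cand)) next
    errs <- pmin(err_gt[cand], err_le[cand])
    i <- cand[which.min(errs)]
    e <- min(err_gt[i], err_le[i])
    if (e < best$err) {
      best <- list(err = e, feature = j,
                   threshold = (xo[i] + xo[i + 1]) / 2,
                   dir = if (err_gt[i] <= err_le[i]) 1 else -1)
    }
  }
  if (!is.finite(best$err)) best <- list(err = 0.5, feature = features[1],
                                         threshold = Inf, dir = 1)
  best
}

#' @noRd
predict_class_stump <- function(stump, X) {
  p <- as.integer(X[, stump$feature] > stump$threshold)
  if (stump$dir < 0) p <- 1L - p
  p  # in {0,1}
}

#' Regression stump minimising SSE (for gradient boosting)
#' @noRd
fit_reg_stump <- function(X, r, features) {
  best <- list(sse = Inf)
  n <- length(r)
  for (j in features) {
    x <- X[, j]; ord <- order(x)
    xo <- x[ord]; ro <- r[ord]
    cl <- cumsum(ro); cl2 <- cumsum(ro^2)
    tot <- cl[n]; tot2 <- cl2[n]
    cand <- which(diff(xo) > 0)
    if (!length(cand)) next
    nl <- cand
    sse <- (cl2[cand] - cl[cand]^2 / nl) +
           ((tot2 - cl2[cand]) - (tot - cl[cand])^2 / (n - nl))
    i <- cand[which.min(sse)]
    if (sse[which(cand == i)] < best$sse) {
      best <- list(sse = sse[which(cand == i)], feature = j,
                   threshold = (xo[i] + xo[i + 1]) / 2,
                   left = cl[i] / i, right = (tot - cl[i]) / (n - i))
    }
  }
  if (!is.finite(best$sse)) best <- list(sse = Inf, feature = features[1],
                                         threshold = Inf,
                                         left = mean(r), right = mean(r))
  best
}

#' @noRd
predict_reg_stump <- function(stump, X) {
  ifelse(X[, stump$feature] > stump$threshold, stump$right, stump$left)
}

#' Fit one learner, return a score function
#' @noRd
fit_model <- function(X, y, model_kind, hyper, seed) {
  p <- ncol(X)
  with_seed(seed, switch(
    model_kind,
    svm = {
      fit <- glmnet::glmnet(X, factor(y, levels = c(0, 1)),
                            family = "binomial", alpha = 0,
                            lambda = hyper$lambda, standardize = TRUE)
      function(Xn) as.numeric(stats::predict(fit, Xn, type = "response",
                                             s = hyper$lambda))
    },
    rf = , extratrees = {
      mtry <- max(1, floor(sqrt(p)))
      stumps <- lapply(seq_len(hyper$n_trees), function(b) {
        idx <- sample.int(nrow(X), nrow(X), replace = TRUE)
        feats <- sample.int(p, mtry)
        if (model_kind == "rf") {
          fit_class_stump(X[idx, , drop = FALSE], y[idx],
                          rep(1 / length(idx), length(idx)), feats)
        } else {  # extremely randomised: random threshold on a random feature
          j <- feats[1]
          rng <- range(X[, j])
          thr <- stats::runif(1, rng[1], rng[2])
          pred <- as.integer(X[idx, j] > thr)
          dir <- if (!any(pred == 1) ||
                     isTRUE(mean(y[idx][pred == 1]) >= mean(y[idx]))) 1 else -1
          list(feature = j, threshold = thr, dir = dir)
        }
      })
      function(Xn) {
        votes <- vapply(stumps, function(st) predict_class_stump(st, Xn),
                        numeric(nrow(Xn)))
        if (nrow(Xn) == 1) mean(votes) else rowMeans(votes)
      }
    },
    adaboost = {
      n <- nrow(X); w <- rep(1 / n, n)
      stumps <- list(); alphas <- numeric(0)
      for (m in seq_len(hyper$n_trees)) {
        st <- fit_class_stump(X, y, w, seq_len(p))
        pred <- predict_class_stump(st, X)
        err <- max(sum(w * (pred != y)), 1e-10)
        if (err >= 0.5) break
        a <- 0.5 * log((1 - err) / err)
        stumps[[m]] <- st; alphas[m] <- a
        w <- w * exp(a * ifelse(pred != y, 1, -1))
        w <- w / sum(w)
      }
      function(Xn) {
        if (!length(stumps)) return(rep(0.5, nrow(Xn)))
        margin <- Reduce(`+`, lapply(seq_along(stumps), function(m)
          alphas[m] * (2 * predict_class_stump(stumps[[m]], Xn) - 1)))
        1 / (1 + exp(-2 * margin))
      }
    },
    gradboost = {
      nu <- 0.1
      f0 <- log(max(mean(y), 1e-10) / max(1 - mean(y), 1e-10))
      fhat <- rep(f0, nrow(X))
      stumps <- list()
      for (m in seq_len(hyper$n_trees)) {
        pr <- 1 / (1 + exp(-fhat))
        st <- fit_reg_stump(X, y - pr, seq_len(p))
        stumps[[m]] <- st
        fhat <- fhat + nu * predict_reg_stump(st, X)
      }
      function(Xn) {
        fh <- rep(f0, nrow(Xn))
        for (st in stumps) fh <- fh + nu * predict_reg_stump(st, Xn)
        1 / (1 + exp(-fh))
      }
    },
    stop("unknown model_kind: ", model_kind)))
}

#' Documented hyperparameter grids (deliberately tiny)
#' @noRd
model_grid <- function(model_kind) {
  if (model_kind == "svm") lapply(c(0.01, 0.1), function(l) list(lambda = l))
  else lapply(c(50, 100), function(k) list(n_trees = k))
}

#' Stratified fold assignment
#' @noRd
stratified_folds <- function(labels, folds, seed) {
  with_seed(seed, {
    assign <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
    assign
  })
}

#' Stratified k-fold cross-validation of a classifier
#'
#' Splits samples into `folds` stratified folds, selects hyperparameters
#' by a small grid search *inside* each training fold (inner stratified
#' 3-fold AUROC), and returns out-of-fold probability scores for every
#' sample plus per-fold and pooled metrics.
#'
#' @param X numeric samples x features matrix.
#' @param labels 0/1 (or logical) outcome, positive class = 1.
#' @param model_kind one of `"svm"`, `"rf"`, `"adaboost"`, `"gradboost"`,
#'   `"extratrees"`.
#' @param folds number of folds (default 5); every fold must contain both
#'   classes.
#' @param seed integer seed controlling fold assignment and learners.
#' @return An `EvalReport`: list with `scores` (out-of-fold), `folds`
#'   (assignment), `per_fold` (data frame of fold metrics), `auroc`,
#'   `auprc`, `f1` (means over folds), and `pooled` metrics on the
#'   concatenated out-of-fold scores.
#' @export
cross_validate <- function(X, labels,
                           model_kind = c("svm", "rf", "adaboost",
                                          "gradboost", "extratrees"),
                           folds = 5, seed = 1) {
  model_kind <- match.arg(model_kind)
  stopifnot(folds >= 2)
  y <- as.integer(as.logical(labels))
  if (min(table(y)) < folds)
    stop("stratification error: a class has fewer samples than folds")
  assign <- stratified_folds(y, folds, seed)
  scores <- numeric(length(y))
  per_fold <- list()
  for (f in seq_len(folds)) {
    tr <- assign != f; te <- !tr
    if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2)
      stop("stratification error: a class is absent from a fold")
    grid <- model_grid(model_kind)
    hyper <- grid[[1]]
    if (length(grid) > 1) {  # inner grid search on training data only
      inner <- stratified_folds(y[tr], 3, seed + 17 * f)
      inner_auc <- vapply(grid, function(h) {
        mean(vapply(1:3, function(g) {
          itr <- inner != g
          if (length(unique(y[tr][!itr])) < 2) return(NA_real_)
          sc <- fit_model(X[tr, , drop = FALSE][itr, , drop = FALSE],
                          y[tr][itr], model_kind, h,
                          seed + 1000L * f + g)(
            X[tr, , drop = FALSE][!itr, , drop = FALSE])
          auroc(sc, y[tr][!itr])
        }, numeric(1)), na.rm = TRUE)
      }, numeric(1))
      hyper <- grid[[which.max(inner_auc)]]
    }
    predict_fn <- fit_model(X[tr, , drop = FALSE], y[tr], model_kind,
                            hyper, seed + 31L * f)
    scores[te] <- predict_fn(X[te, , drop = FALSE])
    per_fold[[f]] <- data.frame(fold = f,
                                auroc = auroc(scores[te], y[te]),
                                auprc = auprc(scores[te], y[te]),
                                f1 = f1_score(scores[te], y[te]))
  }
  pf <- do.call(rbind, per_fold)
  structure(list(model = model_kind, scores = scores, folds = assign,
                 per_fold = pf, auroc = mean(pf$auroc),
                 auprc = mean(pf$auprc), f1 = mean(pf$f1),
                 pooled = list(auroc = auroc(scores, y),
                               auprc = auprc(scores, y),
                               f1 = f1_score(scores, y))),
            class = "EvalReport")
}

#' @exportS3Method base::print
print.EvalReport <- function(x, ...) {
  cat(sprintf("EvalReport [%s]: mean AUROC %.3f, AUPRC %.3f, F1 %.3f over %d folds\n",
              x$model, x$auroc, x$auprc, x$f1, nrow(x$per_fold)))
  invisible(x)
}
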