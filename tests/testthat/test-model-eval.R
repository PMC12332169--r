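test_that("auroc matches pair counting and handles ties", {
  expect_equal(auroc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(auroc(c(3, 2, 1, 0), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
  set.seed(1)
  for (i in 1:20) {
    s <- sample(rnorm(15))  # with occasional ties via rounding
    s <- round(s, 1)
    y <- rbinom(15, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auroc(s, y), auroc_pairs(s, y), tolerance = 1e-12)
  }
})

test_that("auroc is invariant under strictly increasing transforms", {
  set.seed(2)
  s <- rnorm(40); y <- rbinom(40, 1, 0.4)
  expect_equal(auroc(s, y), auroc(exp(s), y))
  expect_equal(auroc(s, y), auroc(3 * s + 7, y))
  expect_equal(auprc(s, y), auprc(exp(s), y), tolerance = 1e-12)
})

test_that("auprc and f1 behave on canonical cases", {
  # perfect separation: AP = 1
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # all-tied scores: AP = prevalence
  expect_equal(auprc(rep(0.3, 10), rep(c(1, 0), 5)), 0.5)
  expect_equal(f1_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(f1_score(c(0.9, 0.2), c(0, 1)), 0)
})

test_that("placement-value AUROC equals the Mann-Whitney AUROC", {
  set.seed(3)
  for (i in 1:10) {
    s <- rnorm(30); y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    dl <- delong_test(s, s, y)
    expect_equal(dl$auc_a, auroc(s, y), tolerance = 1e-12)
  }
})

test_that("delong_test is null on identical scores and sane otherwise", {
  set.seed(4)
  s <- rnorm(40); y <- rep(c(1, 0), c(14, 26))
  dl <- delong_test(s, s, y)
  expect_equal(dl$z, 0)
  expect_equal(dl$p_value, 1)

  # a clearly better model gets a small p
  good <- y + rnorm(40, sd = 0.3)
  bad <- rnorm(40)
  expect_lt(delong_test(good, bad, y)$p_value, 0.05)
})

test_that("DeLong variance tracks the jackknife within 10%", {
  set.seed(5)
  ratios <- replicate(100, {
    y <- rep(c(1, 0), c(14, 26))
    s <- rnorm(40) + 0.8 * y
    delong_variance(s, y) / jackknife_auroc_var(s, y)
  })
  expect_true(all(ratios > 0.9 & ratios < 1.1))
})

test_that("DeLong p-values are uniform under label permutation", {
  set.seed(6)
  sa <- rnorm(60); sb <- 0.5 * sa + rnorm(60)
  y0 <- rep(c(1, 0), each = 30)
  p <- replicate(500, delong_test(sa, sb, sample(y0))$p_value)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))$statistic
  expect_lt(ks, 0.1)
})

test_that("bootstrap_ci is reproducible and covers the estimate", {
  y <- rep(c(1, 0), c(10, 10))
  perfect <- c(rnorm(10, 5), rnorm(10, -5))
  ci <- bootstrap_ci(perfect, y, auroc, n_boot = 200, seed = 3)
  expect_equal(unname(ci), c(1, 1))
  expect_identical(bootstrap_ci(perfect, y, auroc, n_boot = 200, seed = 3),
                   bootstrap_ci(perfect, y, auroc, n_boot = 200, seed = 3))

  set.seed(7)
  cover <- replicate(200, {
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) return(NA)
    s <- rnorm(40) + 0.5 * y
    ci <- bootstrap_ci(s, y, auroc, n_boot = 100,
                       seed = sample.int(1e6, 1))
    est <- auroc(s, y)
    est >= ci[1] - 1e-9 && est <= ci[2] + 1e-9
  })
  expect_true(all(stats::na.omit(cover)))
})

test_that("cross-validation separates signal from noise", {
  set.seed(8)
  n <- 60
  y <- rep(c(1, 0), each = n / 2)
  X <- matrix(rnorm(n * 5), n, 5)
  X[, 3] <- y * 2 + rnorm(n, sd = 0.01)  # one perfectly informative feature
  colnames(X) <- paste0("f", 1:5)
  # boosting sees every feature: perfect separation is exact
  for (mk in c("adaboost", "gradboost")) {
    cv <- cross_validate(X, y, mk, folds = 5, seed = 1)
    expect_equal(cv$auroc, 1, tolerance = 1e-9)
  }
  # feature-subsampled forests dilute the signal slightly but stay near 1
  for (mk in c("rf", "extratrees")) {
    cv <- cross_validate(X, y, mk, folds = 5, seed = 1)
    expect_gt(cv$auroc, 0.9)
  }
  cv_svm <- cross_validate(X, y, "svm", folds = 5, seed = 1)
  expect_gt(cv_svm$auroc, 0.95)

  # random labels: mean AUROC over replicates sits in the null band
  null_auc <- vapply(1:5, function(r) {
    set.seed(100 + r)
    y0 <- sample(y)
    X0 <- matrix(rnorm(n * 5), n, 5)
    cross_validate(X0, y0, "rf", folds = 5, seed = r)$auroc
  }, numeric(1))
  expect_gt(mean(null_auc), 0.35)
  expect_lt(mean(null_auc), 0.65)

  # same seed -> identical folds and scores
  cv_a <- cross_validate(X, y, "extratrees", folds = 5, seed = 4)
  cv_b <- cross_validate(X, y, "extratrees", folds = 5, seed = 4)
  expect_identical(cv_a$folds, cv_b$folds)
  expect_identical(cv_a$scores, cv_b$scores)

  expect_error(cross_validate(X[1:6, ], c(1, 1, 1, 1, 0, 0), "rf",
                              folds = 5), "stratification")
})
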