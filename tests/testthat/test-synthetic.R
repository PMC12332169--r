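test_that("spec validation catches degenerate cohorts", {
  expect_error(synthetic_spec(n_case = 1), ">= 2 samples")
  expect_error(synthetic_spec(n_control = 1), ">= 2 samples")
  expect_error(synthetic_spec(n_genes = 20, deg_fraction = 1,
                              mediator_count = 5), "exceed")
})

test_that("zero effect and zero noise give identical groups", {
  spec <- synthetic_spec(n_genes = 50, n_case = 3, n_control = 3,
                         deg_effect = 0, mediator_count = 0,
                         noise_sd = 0, seed = 1)
  coh <- generate_cohort(spec)
  case <- coh$expr$values[, group_samples(coh$expr, "case")]
  ctrl <- coh$expr$values[, group_samples(coh$expr, "control")]
  expect_equal(case, ctrl, ignore_attr = TRUE)
})

test_that("generators are pure functions of the seed", {
  spec <- synthetic_spec(n_genes = 80, n_case = 4, n_control = 6, seed = 5)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
  g <- sprintf("G%02d", 1:40)
  expect_identical(
    generate_network(g, g[1:2], g[3:12], seed = 3)$edges,
    generate_network(g, g[1:2], g[3:12], seed = 3)$edges)
  expect_identical(
    generate_single_cell(c(a = 5, b = 5), g, seed = 2)$counts,
    generate_single_cell(c(a = 5, b = 5), g, seed = 2)$counts)
})

test_that("planted DEGs are recoverable by a direct t-test oracle", {
  spec <- synthetic_spec(n_genes = 500, deg_fraction = 0.1,
                         deg_effect = 2, seed = 7)
  coh <- generate_cohort(spec)
  case <- coh$expr$values[, group_samples(coh$expr, "case")]
  ctrl <- coh$expr$values[, group_samples(coh$expr, "control")]
  p <- vapply(seq_len(nrow(case)), function(i)
    stats::t.test(case[i, ], ctrl[i, ])$p.value, numeric(1))
  hit <- p.adjust(p, "BH") <= 0.05
  degs <- coh$truth$role == "deg"
  expect_gte(mean(hit[degs]), 0.9)
})

test_that("case-mean shifts match the planted truth", {
  spec <- synthetic_spec(n_genes = 400, n_case = 200, n_control = 200,
                         deg_effect = 1.5, seed = 3)
  coh <- generate_cohort(spec)
  case <- coh$expr$values[, group_samples(coh$expr, "case")]
  ctrl <- coh$expr$values[, group_samples(coh$expr, "control")]
  obs_shift <- rowMeans(case) - rowMeans(ctrl)
  expect_equal(obs_shift, setNames(coh$truth$shift, coh$truth$gene),
               tolerance = 0.3)
  # half of the DEGs up, half down
  deg_shift <- coh$truth$shift[coh$truth$role == "deg"]
  expect_equal(sum(deg_shift > 0), sum(deg_shift < 0))
  expect_true(all(abs(coh$truth$shift[coh$truth$role == "mediator"]) <=
                  spec$deg_noise))
})

test_that("network generator wires mediators as hubs", {
  genes <- sprintf("G%03d", 1:50)
  expect_error(generate_network(genes, genes[1], attach_m = 50, seed = 1),
               "attach_m")
  # preferential attachment with m = 2: 1 + 2 * (n - 2) backbone edges
  net0 <- generate_network(genes, character(0), seed = 2, attach_m = 2)
  expect_equal(nrow(net0$edges), 1 + 2 * 48)
  g <- igraph::graph_from_data_frame(net0$edges, directed = FALSE)
  expect_true(igraph::is_connected(g))

  meds <- genes[1:3]; degs <- genes[11:40]
  net <- generate_network(genes, meds, degs, seed = 2,
                          wire_per_mediator = 20)
  deg_tab <- table(c(net$edges$source, net$edges$target))
  expect_gt(min(deg_tab[meds]),
            stats::median(deg_tab[setdiff(genes, meds)]))
  # every mediator touches >= 20 planted DEGs
  for (m in meds) {
    nb <- c(net$edges$target[net$edges$source == m],
            net$edges$source[net$edges$target == m])
    expect_gte(length(intersect(nb, degs)), 20)
  }
})

test_that("single-cell markers are elevated in their own type only", {
  genes <- sprintf("G%03d", 1:60)
  markers <- list(alpha = genes[1:5], beta = genes[6:10])
  sc <- generate_single_cell(c(alpha = 40, beta = 40, gamma = 40), genes,
                             markers, elevation = 2, seed = 4)
  expect_error(generate_single_cell(c(alpha = 1, beta = 5), genes),
               ">= 2 cells")
  for (ty in names(markers)) {
    own <- colMeans(sc$counts[sc$labels == ty, markers[[ty]]])
    other <- colMeans(sc$counts[sc$labels != ty, markers[[ty]]])
    expect_true(all(own > other))
    expect_gt(mean(own) / mean(other), 1.5)
  }
})

test_that("null single-cell generator is ANOVA-calibrated", {
  genes <- sprintf("G%04d", 1:2000)
  sc <- generate_single_cell(c(a = 50, b = 50, c = 50), genes,
                             elevation = 1, seed = 6)
  prof <- celltype_stats(sc$counts, sc$labels)
  frac <- mean(prof$anova$p_value < 0.05)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.08)
  ks <- suppressWarnings(
    stats::ks.test(prof$anova$p_value, "punif"))$statistic
  expect_lt(ks, 0.1)
})
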