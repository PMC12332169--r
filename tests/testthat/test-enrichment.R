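test_that("hypergeometric p matches closed form and enumeration", {
  bg <- sprintf("g%02d", 1:10)
  coll <- gene_set_collection(list(S = bg[1:5]))
  res <- hypergeom_ora(bg[1:5], coll, bg, min_size = 1, max_size = 10)
  expect_equal(res$p_value, 1 / choose(10, 5), tolerance = 1e-12)

  # a = 0 -> p = 1
  res0 <- hypergeom_ora(bg[6:10], coll, bg, min_size = 1, max_size = 10)
  expect_equal(res0$p_value, 1)

  # full enumeration oracle for N <= 12
  for (case in list(c(N = 10, K = 4, n = 3), c(N = 12, K = 6, n = 5),
                    c(N = 8, K = 3, n = 4))) {
    N <- case["N"]; K <- case["K"]; n <- case["n"]
    bgx <- sprintf("u%02d", seq_len(N))
    collx <- gene_set_collection(list(S = bgx[seq_len(K)]))
    for (a in 0:min(K, n)) {
      # query with exactly a hits
      q <- c(bgx[seq_len(a)], rev(bgx)[seq_len(n - a)])
      res <- hypergeom_ora(q, collx, bgx, min_size = 1, max_size = 12)
      expect_equal(res$p_value, hyper_upper_enum(N, K, n, a),
                   tolerance = 1e-12)
    }
  }
})

test_that("size filters and background validation apply", {
  bg <- sprintf("g%03d", 1:100)
  coll <- gene_set_collection(list(small = bg[1:9], ok = bg[1:20]))
  res <- hypergeom_ora(bg[1:10], coll, bg, min_size = 10, max_size = 500)
  expect_identical(res$name, "ok")
  expect_error(hypergeom_ora(bg[1:3], coll, character(0)), "empty background")
  expect_warning(hypergeom_ora(c(bg[1:5], "alien"), coll, bg), "dropped")
})

test_that("fisher_overlap reports the sample odds ratio and exact p", {
  # a = 17 of 100 vs a 1665-gene reference in a 20000-gene universe
  res <- fisher_overlap_counts(17, 100, 1665, 20000)
  expect_equal(res$odds_ratio, (17 * 18252) / (83 * 1648), tolerance = 1e-12)
  expect_equal(sprintf("%.8f", res$odds_ratio), "2.26842321")
  # p agrees with the two-sided fisher.test oracle
  ft <- stats::fisher.test(matrix(c(17, 83, 1648, 18252), 2))
  expect_equal(res$p_value, ft$p.value, tolerance = 1e-9)

  # a = 0 -> OR = 0
  expect_equal(fisher_overlap_counts(0, 100, 521, 20000)$odds_ratio, 0)
  # degenerate margins -> infinite OR
  expect_equal(fisher_overlap_counts(5, 5, 10, 100)$odds_ratio, Inf)
  expect_error(fisher_overlap(letters[1:5], letters[3:10],
                              background_size = 5), "smaller")
})

test_that("overlap OR and p are symmetric in query and reference", {
  q <- sprintf("q%02d", 1:30)
  r <- c(q[1:7], sprintf("r%02d", 1:50))
  a <- fisher_overlap(q, r, 1000)
  b <- fisher_overlap(r, q, 1000)
  expect_equal(a$odds_ratio, b$odds_ratio, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("BH-adjusted ORA p-values are monotone in p-rank", {
  set.seed(8)
  bg <- sprintf("g%03d", 1:300)
  coll <- gene_set_collection(lapply(setNames(1:20, paste0("S", 1:20)),
                                     function(i) sample(bg, 25)))
  res <- hypergeom_ora(sample(bg, 40), coll, bg, min_size = 5,
                       max_size = 200)
  expect_true(all(diff(res$adj_p[order(res$p_value)]) >= -1e-12))
  expect_true(all(res$adj_p >= 0 & res$adj_p <= 1))
})

test_that("reduce_redundancy keeps the best of near-identical terms", {
  mem <- list(A = letters[1:10], B = letters[1:10], C = letters[11:20])
  res <- data.frame(name = c("A", "B", "C"), adj_p = c(0.001, 0.01, 0.02))
  out <- reduce_redundancy(res, mem, cutoff = 0.8)
  expect_identical(out$name, c("A", "C"))  # identical twin dropped

  # disjoint sets all survive
  mem2 <- list(A = letters[1:5], B = letters[6:10], C = letters[11:15])
  expect_equal(nrow(reduce_redundancy(res, mem2, 0.8)), 3)

  # greedy chain: A~B similar, B~C similar, A~C not -> keep {A, C}
  mem3 <- list(A = sprintf("x%02d", 1:10),
               B = sprintf("x%02d", c(1:9, 11)),
               C = sprintf("x%02d", c(1:8, 11, 12)))
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  stopifnot(jac(mem3$A, mem3$B) > 0.8, jac(mem3$B, mem3$C) > 0.8,
            jac(mem3$A, mem3$C) < 0.8)
  out3 <- reduce_redundancy(res, mem3, cutoff = 0.8)
  expect_identical(out3$name, c("A", "C"))
})
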