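test_that("kendall_tau matches closed forms and brute-force pair counting", {
  expect_equal(kendall_tau(1:5, 1:5)$tau, 1.0)
  expect_equal(kendall_tau(1:3, 3:1)$tau, -1.0)
  # 4 concordant, 2 discordant of C(4,2)=6 point pairs
  expect_equal(kendall_tau(c(1, 2, 3, 4), c(2, 1, 4, 3))$tau, 1 / 3,
               tolerance = 1e-12)

  set.seed(42)
  for (rep in 1:10) {
    x <- sample(1:8, 12, replace = TRUE)  # with ties
    y <- rnorm(12)
    expect_equal(kendall_tau(x, y)$tau, brute_tau_b(x, y), tolerance = 1e-12)
  }
  expect_error(kendall_tau(1:4, 1:5), "equal length")
  expect_error(kendall_tau(1:2, 1:2), "at least 3")
})

test_that("kendall_tau is invariant under monotone transforms and antisymmetric", {
  set.seed(7)
  x <- rnorm(30); y <- rnorm(30)
  base <- kendall_tau(x, y)
  expect_equal(kendall_tau(exp(x), y)$tau, base$tau)
  expect_equal(kendall_tau(x, y^3 + 5 * y)$tau, base$tau)
  expect_equal(kendall_tau(x, -y)$tau, -base$tau)
})

test_that("generator tau calibration approaches the arcsine law", {
  set.seed(123)
  pe <- simulate_pair_expression(2000, 0.5)
  expect_equal(kendall_tau(pe$x, pe$y)$tau, 0.5, tolerance = 0.03)
  pe0 <- simulate_pair_expression(2000, 0)
  expect_lt(abs(kendall_tau(pe0$x, pe0$y)$tau), 0.05)
})

test_that("screen_pairs applies the significance threshold and preconditions", {
  set.seed(11)
  n <- 40
  expr <- matrix(rnorm(4 * n, 8), nrow = 4,
                 dimnames = list(c("a1", "a2", "b1", "b2"), paste0("S", 1:n)))
  # correlated pair p1, independent pair p2
  expr["a2", ] <- expr["a1", ] + rnorm(n, sd = 0.4)
  b <- cohort_bundle(expr, make_clinical(colnames(expr)), "c1")
  pairs <- data.frame(pair_id = c("p1", "p2"), gene_a = c("a1", "b1"),
                      gene_b = c("a2", "b2"),
                      orientation = "divergent", class_tag = "SAGP",
                      stringsAsFactors = FALSE)
  res <- screen_pairs(b, pairs, alpha = 0.05)
  expect_equal(nrow(res$records), 2L)
  expect_true("p1" %in% res$significant$pair_id)
  expect_false("p2" %in% res$significant$pair_id)
  expect_true(all(res$significant$p_value < 0.05))
  expect_error(screen_pairs(b, pairs, subgroup = c("S1", "S2")),
               "fewer than 3")
})

test_that("select_representative keeps the strongest-|tau| candidate with ties lexicographic", {
  set.seed(5)
  n <- 30
  expr <- matrix(rnorm(6 * n, 8), nrow = 6,
                 dimnames = list(c("pA", "pB", "qA", "qB", "rA", "rB"),
                                 paste0("S", 1:n)))
  expr["pB", ] <- expr["pA", ] + rnorm(n, sd = 0.3)      # strong positive
  expr["qB", ] <- -2 * expr["qA", ] + rnorm(n, sd = 0.1) # stronger negative
  b <- cohort_bundle(expr, make_clinical(colnames(expr)), "c1")
  cand <- data.frame(feature_a = c("pA", "qA"), feature_b = c("pB", "qB"),
                     stringsAsFactors = FALSE)
  best <- select_representative(cand, b)
  expect_equal(best$feature_a, "qA")  # negative but larger magnitude
  expect_lt(best$tau, 0)

  one <- select_representative(cand[1, ], b)
  expect_equal(one$feature_a, "pA")
  # exact tie: identical candidate duplicated under two names
  expr2 <- expr
  rownames(expr2)[5:6] <- c("aaA", "aaB")
  expr2["aaA", ] <- expr["pA", ]; expr2["aaB", ] <- expr["pB", ]
  b2 <- cohort_bundle(expr2, make_clinical(colnames(expr2)), "c1")
  tie <- select_representative(
    data.frame(feature_a = c("pA", "aaA"), feature_b = c("pB", "aaB"),
               stringsAsFactors = FALSE), b2)
  expect_equal(tie$feature_a, "aaA")  # lexicographically first
  expect_error(select_representative(cand[0, ], b), "no candidate")
})

test_that("hypergeometric co-occurrence equals exact enumeration", {
  u <- letters[1:10]
  expect_equal(cooccurrence_hypergeom(u[1:5], u[2:5], u), 5 / 210,
               tolerance = 1e-12)
  expect_equal(cooccurrence_hypergeom(u[1:5], u[6:9], u), 1)  # P(X >= 0) = 1
  expect_equal(cooccurrence_hypergeom(u, u[1:4], u), 1)
  expect_error(cooccurrence_hypergeom(c(u, "zz"), u[1:2], u), "subsets")

  # exhaustive enumeration oracle for small universes
  set.seed(9)
  for (rep in 1:5) {
    N <- sample(6:12, 1)
    u <- paste0("g", 1:N)
    A <- sample(u, sample(2:(N - 1), 1))
    B <- sample(u, sample(2:(N - 1), 1))
    k <- length(intersect(A, B))
    draws <- combn(u, length(B))
    tail_p <- mean(apply(draws, 2, function(d) length(intersect(A, d)) >= k))
    expect_equal(cooccurrence_hypergeom(A, B, u), tail_p, tolerance = 1e-10)
  }
})

test_that("tau-distribution comparison reproduces hand-stepped KS statistics", {
  recs <- function(v) data.frame(tau = v)
  same <- compare_tau_distributions(recs(c(0.1, 0.2, 0.3)), recs(c(0.1, 0.2, 0.3)))
  expect_equal(same$D, 0)
  expect_gte(same$p, 0.999)
  dis <- compare_tau_distributions(recs(c(0.1, 0.2, 0.3)), recs(c(0.7, 0.8, 0.9)))
  expect_equal(dis$D, 1.0)
  mix <- compare_tau_distributions(recs(c(0.1, 0.5, 0.9)), recs(c(0.2, 0.6)))
  expect_equal(mix$D, 1 / 3, tolerance = 1e-12)
  expect_equal(nrow(mix$ecdf_a), 3L)
  expect_error(compare_tau_distributions(recs(0.1), recs(c(0.1, 0.2, 0.3))),
               "at least 2")
})
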