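test_that("BH adjustment follows the step-up formula and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.05), 0.05)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0,1\\]")
  set.seed(11)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  # monotone: adjustment preserves the ordering (plateaus allowed)
  expect_true(all(diff(adj[order(p)]) >= 0))
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), adj[perm])
  # a flat plateau is a fixed point
  expect_equal(bh_adjust(rep(0.04, 4)), rep(0.04, 4))
})

test_that("point-biserial correlation matches hand computation", {
  expect_equal(point_biserial(c(1, 1, 0, 0), c(1, 1, 0, 0))$r, 1)
  d <- point_biserial(c(2, 2, 2, 2), c(1, 1, 0, 0))
  expect_equal(d$r, 0)
  expect_true(d$degenerate)
  expect_equal(point_biserial(c(3, 1, 2, 0), c(1, 1, 0, 0))$r, 1 / sqrt(5))
  expect_error(point_biserial(c(1, 2), c(1, 1)), "both labels")
})

test_that("exact Mann-Whitney U equals full enumeration for small samples", {
  res <- mwu_exact(1:3, 4:6)
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)
  expect_true(res$exact)

  set.seed(42)
  for (n1 in 2:5) for (n2 in 2:5) {
    if (n1 + n2 > 10) next
    for (rep in 1:4) {
      vals <- sample(10000, n1 + n2)  # distinct -> no ties
      a <- vals[seq_len(n1)]; b <- vals[-seq_len(n1)]
      res <- mwu_exact(a, b)
      expect_true(res$exact)
      expect_equal(res$p, mwu_enum_p(a, b), tolerance = 1e-12)
      expect_true(res$U >= 0 && res$U <= n1 * n2)
    }
  }
})

test_that("tied or large Mann-Whitney inputs use the corrected approximation", {
  res <- mwu_exact(c(1, 2, 3), c(1, 2, 3))
  expect_false(res$exact)
  expect_equal(res$p, 1, tolerance = 1e-9)
  big <- mwu_exact(rnorm(15), rnorm(15))
  expect_false(big$exact)
  expect_true(big$p >= 0 && big$p <= 1)
  expect_error(mwu_exact(numeric(0), 1:3), "non-empty")
})

test_that("chi-square contingency tests reproduce clinical-table statistics", {
  r1 <- suppressWarnings(chisq_contingency(matrix(c(3, 9, 6, 2), 2)))
  expect_equal(r1$statistic, 3.0388, tolerance = 1e-4)
  expect_equal(r1$df, 1)
  expect_equal(round(r1$p, 3), 0.081)
  expect_equal(r1$method, "chi-square-yates")

  r2 <- suppressWarnings(chisq_contingency(rbind(c(3, 6), c(1, 0), c(2, 0))))
  expect_equal(r2$statistic, 4)
  expect_equal(r2$df, 2)
  expect_equal(round(r2$p, 3), 0.135)
  expect_equal(r2$method, "chi-square")

  r3 <- suppressWarnings(chisq_contingency(matrix(c(6, 0, 4, 2), 2)))
  expect_equal(r3$statistic, 0.6, tolerance = 1e-9)
  expect_equal(round(r3$p, 3), 0.439)

  # transposition invariance
  set.seed(5)
  tb <- matrix(rpois(6, 8) + 1, 2, 3)
  a <- suppressWarnings(chisq_contingency(tb))
  b <- suppressWarnings(chisq_contingency(t(tb)))
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p, b$p)

  expect_error(chisq_contingency(rbind(c(0, 0), c(1, 2))), "margins")
})

test_that("Fisher exact p sums hypergeometric probabilities two-sidedly", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 4, 1, 5), 2))$p, 1)
  expect_equal(fisher_exact_2x2(matrix(c(3, 9, 6, 2), 2))$p, 0.06477733,
               tolerance = 1e-7)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))$p, 2 / choose(10, 5),
               tolerance = 1e-12)
  # symmetric under row and column swaps
  set.seed(8)
  for (i in 1:5) {
    tb <- matrix(rpois(4, 5) + 1, 2)
    p0 <- fisher_exact_2x2(tb)$p
    expect_equal(fisher_exact_2x2(tb[2:1, ])$p, p0)
    expect_equal(fisher_exact_2x2(tb[, 2:1])$p, p0)
  }
})

test_that("hypergeometric ORA matches the one-sided Fisher test", {
  g <- sprintf("g%03d", 1:20)
  sets <- list(S1 = list(description = "d", genes = g[1:5]))
  res <- ora_hypergeom(g[1:5], g, sets)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)

  sets2 <- list(S1 = list(description = "d", genes = g[1:4]))
  expect_equal(ora_hypergeom(g[10:14], g, sets2)$p, 1, tolerance = 1e-9)

  expect_error(ora_hypergeom(c("g001", "nope"), g, sets), "nope")

  # equivalence with one-sided fisher.test on the induced 2x2
  set.seed(9)
  for (i in 1:10) {
    N <- sample(30:80, 1)
    uni <- sprintf("u%03d", seq_len(N))
    set_g <- sample(uni, sample(5:15, 1))
    hits <- sample(uni, sample(5:20, 1))
    res <- ora_hypergeom(hits, uni, list(S = list(description = "", genes = set_g)))
    x <- res$overlap
    tb <- matrix(c(x, res$set_size - x,
                   res$draw_size - x,
                   N - res$set_size - res$draw_size + x), 2)
    expect_equal(res$p, fisher.test(tb, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("ROC AUC equals brute-force pair counting and is rank-invariant", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.9, 0.2, 0.8, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")

  set.seed(10)
  for (i in 1:10) {
    n <- sample(6:50, 1)
    sc <- sample(round(rnorm(n), 1))  # some ties
    lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- c(TRUE, FALSE)
    a <- roc_auc(sc, lab)
    expect_equal(a, auc_brute(sc, lab), tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(roc_auc(exp(sc), lab), a, tolerance = 1e-12)
  }
})

test_that("ROC AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  for (i in 1:5) {
    sc <- rnorm(30)
    lab <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- c(TRUE, FALSE)
    ref <- as.numeric(pROC::auc(pROC::roc(response = lab, predictor = sc,
                                          levels = c(FALSE, TRUE),
                                          direction = "<", quiet = TRUE)))
    expect_equal(roc_auc(sc, lab), ref, tolerance = 1e-12)
  }
})

test_that("Welch t test is calibrated and detects separation", {
  x <- c(1.2, 2.3, 3.1, 4.5)
  same <- welch_t(x, x)
  expect_equal(same$p, 1, tolerance = 1e-9)
  shift <- welch_t(c(0, 0.01), c(10, 10.01))
  expect_lt(shift$p, 0.05)
  expect_error(welch_t(c(1, 1), c(2, 2)), "degenerate")
  # p uniform under the null
  set.seed(13)
  p <- replicate(2000, welch_t(rnorm(5), rnorm(5))$p)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})
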