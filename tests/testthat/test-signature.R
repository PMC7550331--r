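make_outcome_expression <- function(seed = 1, n_genes = 30, n_poor = 6,
                                    n_good = 6) {
  set.seed(seed)
  st <- make_sample_table(n_poor, n_good, 0)
  em <- matrix(rnorm(n_genes * nrow(st), mean = 5), n_genes, nrow(st),
               dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                               st$sample_id))
  list(em = em, st = st)
}

test_that("genes are ranked by |r| with lexicographic tie-break", {
  d <- make_outcome_expression()
  # plant a perfect tracker
  d$em["g001", ] <- as.numeric(d$st$outcome == "poor") * 4 + 1
  rk <- rank_by_outcome_correlation(d$em, d$st)
  expect_equal(rk$gene_id[1], "g001")
  expect_equal(abs(rk$r[1]), 1)
  expect_equal(rk$rank, seq_len(nrow(rk)))

  # exact tie: duplicated gene rows rank lexicographically
  em2 <- d$em[c("g005", "g003"), ]
  rownames(em2) <- c("zz", "aa")
  em2["zz", ] <- em2["aa", ]
  rk2 <- rank_by_outcome_correlation(em2, d$st)
  expect_equal(rk2$gene_id, c("aa", "zz"))
})

test_that("ranking equals an independent brute-force recomputation", {
  d <- make_outcome_expression(seed = 2)
  rk <- rank_by_outcome_correlation(d$em, d$st)
  y <- as.numeric(d$st$outcome == "poor")
  r_manual <- apply(d$em, 1, function(x) cor(x, y))
  ord <- order(-abs(r_manual), names(r_manual))
  expect_equal(rk$gene_id, names(r_manual)[ord])
  expect_equal(rk$r, unname(r_manual[ord]), tolerance = 1e-12)
})

test_that("LOO centroid correlations match the hand-computed toy case", {
  # held-out poor sample [1,2,3]; remaining poor centroid [2,4,6], good
  # centroid [3,2,1]: c_poor = 1, c_good = -1 (Pearson on 3 points)
  em <- cbind(p01 = c(1, 2, 3), p02 = c(2, 4, 6), p03 = c(2, 4, 6),
              g01 = c(3, 2, 1), g02 = c(3, 2, 1))
  rownames(em) <- c("gA", "gB", "gC")
  st <- make_sample_table(3, 2, 0)
  rec <- loo_centroid_classify(em, st, rownames(em))
  i <- rec$sample_id == "p01"
  expect_equal(rec$c_poor[i], 1)
  expect_equal(rec$c_good[i], -1)
  expect_equal(rec$score[i], 2)
  expect_equal(rec$distance[i], 2 / sqrt(2))
  expect_equal(rec$predicted[i], "poor")
})

test_that("LOO scores equal a naive loop reimplementation on random cohorts", {
  for (seed in 1:5) {
    d <- make_outcome_expression(seed = seed, n_genes = sample(5:50, 1))
    rec <- loo_centroid_classify(d$em, d$st, rownames(d$em))
    ref <- loo_naive(d$em, d$st$outcome)
    expect_equal(rec$c_poor, ref$c_poor, tolerance = 1e-12)
    expect_equal(rec$c_good, ref$c_good, tolerance = 1e-12)
    expect_equal(rec$score, ref$score, tolerance = 1e-12)
  }
})

test_that("classification records are invariant to gene order", {
  d <- make_outcome_expression(seed = 7, n_genes = 12)
  genes <- rownames(d$em)
  a <- loo_centroid_classify(d$em, d$st, genes)
  b <- loo_centroid_classify(d$em[rev(genes), ], d$st, rev(genes))
  expect_equal(a, b)
})

test_that("swapping outcome labels negates scores and reflects the AUC", {
  d <- make_outcome_expression(seed = 8, n_genes = 20)
  rec <- loo_centroid_classify(d$em, d$st, rownames(d$em))
  st2 <- d$st
  st2$outcome <- ifelse(st2$outcome == "poor", "good", "poor")
  rec2 <- loo_centroid_classify(d$em, st2, rownames(d$em))
  expect_equal(rec2$score, -rec$score, tolerance = 1e-12)
  auc1 <- roc_auc(rec$score, rec$outcome == "poor")
  # relabelling the same scores reflects the AUC ...
  expect_equal(roc_auc(rec$score, rec$outcome == "good"), 1 - auc1,
               tolerance = 1e-12)
  # ... while the full swap (labels and negated scores) leaves it unchanged
  auc2 <- roc_auc(rec2$score, rec2$outcome == "poor")
  expect_equal(auc2, auc1, tolerance = 1e-12)
})

test_that("the stop rule halts at the first non-improvement or a perfect AUC", {
  expect_equal(cmsig:::choose_k(c(`5` = 0.8, `10` = 0.9, `15` = 0.9), 5), 10)
  expect_equal(cmsig:::choose_k(c(`5` = 1.0), 5), 5)
  expect_equal(cmsig:::choose_k(c(`5` = 0.9, `10` = 0.8), 5), 5)
  expect_equal(cmsig:::choose_k(c(`5` = 0.7, `10` = 0.8, `15` = 0.9), 5), 15)
})

test_that("selection stops at one batch when the top genes separate perfectly", {
  d <- make_outcome_expression(seed = 9, n_genes = 40)
  y <- as.numeric(d$st$outcome == "poor")
  # five heterogeneous strong genes: mixed directions so centroid shapes differ
  for (j in 1:5) {
    d$em[j, ] <- 5 + j + ifelse(j %% 2 == 0, 4, -4) * y + rnorm(12, sd = 0.05)
  }
  m <- select_signature(d$em, d$st, rownames(d$em), batch = 5, k_max = 20)
  expect_s3_class(m, "cm_signature")
  expect_equal(m$k, 5)
  expect_equal(m$auc, 1)
  expect_equal(unname(m$auc_trace), 1)
  expect_setequal(m$genes, rownames(d$em)[1:5])
  # trace and fit are fully deterministic
  m2 <- select_signature(d$em, d$st, rownames(d$em), batch = 5, k_max = 20)
  expect_identical(m$auc_trace, m2$auc_trace)
  expect_identical(m$genes, m2$genes)
  expect_error(select_signature(d$em, d$st, rownames(d$em)[1:3], batch = 5),
               "at least 5")
})

test_that("the decision band uses the sample SD of signed diagonal distances", {
  rec <- data.frame(sample_id = c("a", "b"), outcome = c("poor", "good"),
                    c_poor = c(0.9, 0.1), c_good = c(0.1, 0.9),
                    score = c(0.8, -0.8), distance = c(0.8, -0.8) / sqrt(2),
                    predicted = c("poor", "good"), flagged = FALSE)
  band <- decision_band(rec)
  x <- 0.8 / sqrt(2)
  expect_equal(band$sigma, x * sqrt(2))  # two-point sample SD
  expect_false(any(band$records$confident))

  # identical signed distances: sigma 0, all confident
  rec2 <- rec; rec2$distance <- c(0.5, 0.5); rec2$score <- rep(0.5 * sqrt(2), 2)
  rec2$predicted <- "poor"
  band2 <- decision_band(rec2)
  expect_equal(band2$sigma, 0)
  expect_true(all(band2$records$confident))
  # flags always recomputed consistently from the returned sigma
  expect_equal(band2$records$confident,
               abs(rec2$distance) > band2$sigma &
                 !is.na(rec2$predicted))
  expect_error(decision_band(rec[1, ]), "at least 2")
})

test_that("heatmap export orders rows by correlation and columns by score", {
  d <- make_outcome_expression(seed = 10, n_genes = 25)
  y <- as.numeric(d$st$outcome == "poor")
  for (j in 1:8) d$em[j, ] <- 5 + ifelse(j %% 2 == 0, 3, -3) * y + rnorm(12, sd = 0.3)
  m <- select_signature(d$em, d$st, rownames(d$em), batch = 5, k_max = 10)
  hm <- export_signature_heatmap(d$em, d$st, m)
  sig <- m$ranking[m$ranking$gene_id %in% m$genes, ]
  expect_equal(hm$gene_order, sig$gene_id[order(-sig$r, sig$gene_id)])
  expect_equal(hm$sample_order,
               m$records$sample_id[order(-m$records$score,
                                         m$records$sample_id)])
  expect_equal(rownames(hm$matrix), hm$gene_order)
  expect_equal(colnames(hm$matrix), hm$sample_order)
  # round-trip through TSV
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression(hm$matrix, f)
  expect_equal(read_expression(f), hm$matrix, tolerance = 1e-12)
})

test_that("model methods expose coefficients, predictions and summaries", {
  d <- make_outcome_expression(seed = 11, n_genes = 30)
  y <- as.numeric(d$st$outcome == "poor")
  for (j in 1:6) d$em[j, ] <- 4 + j + ifelse(j %% 2 == 0, 3, -3) * y +
      rnorm(12, sd = 0.2)
  m <- select_signature(d$em, d$st, rownames(d$em), batch = 5, k_max = 15)
  expect_named(coef(m))
  expect_true(all(names(coef(m)) %in% m$genes))
  expect_output(print(m), "Prognostic correlation-centroid signature")
  expect_output(print(summary(m)), "Leave-one-out classification")
  # predict with no newdata returns the LOO records
  expect_identical(predict(m, d$em, d$st), m$records)
  # predicting the training samples from full centroids keeps classes apart
  pr <- predict(m, d$em, d$st, newdata = d$em)
  expect_equal(nrow(pr), ncol(d$em))
  expect_true(all(pr$predicted[d$st$outcome == "poor"] == "poor"))
})

test_that("pure-noise cohorts run to completion with in-sample optimism noted", {
  aucs <- sapply(1:50, function(s) {
    ch <- generate_cohort(cohort_config(n_genes = 500, n_control = 0,
                                        n_poor = 6, n_good = 6,
                                        n_tumor_deg = 0, n_outcome_genes = 0,
                                        seed = 100 + s))
    em <- normalize_counts(ch$counts, size_factors(ch$counts), log = TRUE)
    m <- select_signature(em, ch$samples, rownames(em), batch = 5, k_max = 50)
    expect_true(all(diff(m$auc_trace[seq_len(length(m$auc_trace) - 1)]) > 0) ||
                  length(m$auc_trace) <= 2)
    m$auc
  })
  med <- median(aucs)
  expect_gte(med, 0.4)
  expect_lte(med, 1.0)
})
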