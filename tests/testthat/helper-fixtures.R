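# Small fixtures and independent oracles shared across test files.

tiny_counts <- function() {
  m <- matrix(c(10, 0, 5,
                20, 3, 0), nrow = 3, ncol = 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  storage.mode(m) <- "double"
  m
}

make_sample_table <- function(n_poor = 6, n_good = 6, n_control = 0) {
  n <- n_poor + n_good + n_control
  data.frame(
    sample_id = c(sprintf("p%02d", seq_len(n_poor)),
                  sprintf("g%02d", seq_len(n_good)),
                  if (n_control > 0) sprintf("c%02d", seq_len(n_control))),
    group = c(rep("tumor", n_poor + n_good), rep("control", n_control)),
    outcome = c(rep("poor", n_poor), rep("good", n_good),
                rep("none", n_control)),
    recurrence = c(rep(FALSE, n_poor + n_good), rep(NA, n_control)),
    metastasis = c(rep(FALSE, n_poor + n_good), rep(NA, n_control)),
    batch = rep("b1", n),
    stringsAsFactors = FALSE)
}

# exhaustive two-sided Mann-Whitney p by enumerating label assignments
mwu_enum_p <- function(a, b) {
  vals <- c(a, b)
  n1 <- length(a)
  r <- rank(vals)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  cmb <- utils::combn(length(vals), n1)
  Unull <- apply(cmb, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(Unull <= U), mean(Unull >= U)))
}

# brute-force AUC over all (positive, negative) pairs
auc_brute <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# naive leave-one-out centroid classification with explicit loops
loo_naive <- function(em, outcome) {
  n <- ncol(em)
  out <- data.frame(c_poor = numeric(n), c_good = numeric(n))
  for (i in seq_len(n)) {
    poor_cols <- setdiff(which(outcome == "poor"), i)
    good_cols <- setdiff(which(outcome == "good"), i)
    cp <- numeric(nrow(em)); cg <- numeric(nrow(em))
    for (g in seq_len(nrow(em))) {
      cp[g] <- mean(em[g, poor_cols])
      cg[g] <- mean(em[g, good_cols])
    }
    out$c_poor[i] <- cor(em[, i], cp)
    out$c_good[i] <- cor(em[, i], cg)
  }
  out$score <- out$c_poor - out$c_good
  out
}
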