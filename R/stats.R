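# Shared statistical primitives. Commodity tests delegate to the standard
# stats implementations behind a uniform record interface; the ROC AUC and
# point-biserial correlation used by the signature engine are computed
# directly.

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; input order is preserved and adjusted values are
#' clipped to 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must be finite and in [0,1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Point-biserial correlation of expression with a binary outcome
#'
#' Pearson correlation between a continuous vector and a 0/1-coded label
#' (poor = 1, good = 0). Constant input returns r = 0 with a degenerate flag
#' so downstream ranking never fails on flat genes.
#'
#' @param x numeric vector.
#' @param y binary labels: logical, or 0/1 numeric (1 = positive class).
#' @return list with components \code{r} and \code{degenerate}.
#' @export
point_biserial <- function(x, y) {
  y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 2)
    stop("x and y must have equal length >= 2", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("both labels must be present", call. = FALSE)
  if (stats::sd(x) == 0) return(list(r = 0, degenerate = TRUE))
  list(r = stats::cor(x, y), degenerate = FALSE)
}

#' Mann-Whitney U test
#'
#' U is computed from midranks. The p-value is exact (doubled smaller tail of
#' the exact null distribution, capped at 1) when the combined sample size is
#' at most \code{exact_max} and there are no ties; otherwise a normal
#' approximation with tie and continuity correction is used.
#'
#' @param a,b numeric vectors, both non-empty.
#' @param exact_max largest combined sample size for the exact branch.
#' @return list with \code{U}, \code{p}, and logical \code{exact}.
#' @export
mwu_exact <- function(a, b, exact_max = 20) {
  if (length(a) == 0 || length(b) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  r <- rank(c(a, b))
  n1 <- length(a); n2 <- length(b)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(a, b)))
  use_exact <- (n1 + n2) <= exact_max && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = use_exact,
                                            correct = TRUE))
  list(U = unname(U), p = wt$p.value, exact = use_exact)
}

#' Chi-square test on an r x c contingency table
#'
#' Pearson chi-square with Yates continuity correction applied only to 2x2
#' tables (when \code{yates_for_2x2} is set). Expected counts below 5 are
#' tolerated with a collected warning rather than a rejection, since small
#' clinical cohorts routinely produce them.
#'
#' @param table matrix of non-negative integers, at least 2x2, positive margins.
#' @param yates_for_2x2 apply the continuity correction to 2x2 tables.
#' @return list with \code{statistic}, \code{df}, \code{p}, \code{method}.
#' @export
chisq_contingency <- function(table, yates_for_2x2 = TRUE) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("table must be at least 2x2", call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("table cells must be non-negative integers", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all row and column margins must be positive", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(table, correct = yates_for_2x2))
  if (any(ct$expected < 5))
    warning("expected count < 5 in some cell; chi-square approximation is rough",
            call. = FALSE)
  yates_used <- yates_for_2x2 && nrow(table) == 2 && ncol(table) == 2
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value,
       method = if (yates_used) "chi-square-yates" else "chi-square")
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided p as the sum of hypergeometric probabilities of all tables with
#' the observed margins whose probability does not exceed the observed
#' table's.
#'
#' @param table 2x2 matrix of non-negative integers with positive margins.
#' @return list with \code{statistic} (odds ratio estimate), \code{df} (NA),
#'   \code{p}, \code{method}.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)))
    stop("table must be 2x2", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all margins must be positive", call. = FALSE)
  ft <- stats::fisher.test(table)
  list(statistic = unname(ft$estimate), df = NA_integer_,
       p = ft$p.value, method = "fisher-exact")
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability of drawing at
#' least the observed overlap when \code{length(hits)} genes are drawn from
#' the universe; BH adjustment across the tested sets. Set members outside
#' the universe are ignored.
#'
#' @param hits character vector of selected genes, a subset of \code{universe}.
#' @param universe character vector of all testable genes.
#' @param sets gene-set collection from \code{\link{read_gmt}}.
#' @return data.frame: set_id, overlap, set_size, universe_size, draw_size,
#'   p, padj.
#' @export
ora_hypergeom <- function(hits, universe, sets) {
  universe <- unique(universe)
  hits <- unique(hits)
  out <- setdiff(hits, universe)
  if (length(out) > 0)
    stop("hit gene(s) not in universe: ", paste(out, collapse = ", "),
         call. = FALSE)
  N <- length(universe); k <- length(hits)
  res <- lapply(names(sets), function(id) {
    members <- intersect(sets[[id]]$genes, universe)
    K <- length(members)
    x <- length(intersect(hits, members))
    p <- if (K == 0) 1 else stats::phyper(x - 1, K, N - K, k, lower.tail = FALSE)
    data.frame(set_id = id, overlap = x, set_size = K, universe_size = N,
               draw_size = k, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$padj <- bh_adjust(res$p)
  res
}

#' ROC area under the curve
#'
#' Rank-based AUC: the probability that a random positive scores above a
#' random negative, ties counting one half. The positive class is poor
#' outcome throughout the package.
#'
#' @param scores numeric classification scores.
#' @param labels logical or 0/1; TRUE/1 marks the positive class.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Welch two-sample t test
#'
#' @param a,b numeric vectors, each with at least 2 values and non-zero
#'   variance.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("degenerate variance: both groups are constant", call. = FALSE)
  tt <- stats::t.test(a, b)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}
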