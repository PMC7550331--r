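# Normalisation and negative-binomial Wald differential expression.
#
# The DE test is a transparent NB GLM Wald test: per-gene method-of-moments
# dispersion on normalised counts pooled within groups, then a log-link NB
# GLM (intercept + group indicator, offsets log size factor) fitted by IRLS,
# vectorised across genes since every gene shares the same two-column design.
# Shrinkage, dispersion-trend fitting, outlier filtering and independent
# filtering of full DESeq2-style pipelines are deliberately not part of the
# model; the test's calibration is established by simulation instead.

#' Median-of-ratios size factors
#'
#' The reference is the per-gene geometric mean over samples, computed on
#' genes with positive counts in every sample; each sample's factor is the
#' median ratio of its counts to the reference.
#'
#' @param counts count matrix.
#' @return named numeric vector of positive factors, one per sample.
#' @export
size_factors <- function(counts) {
  validate_counts(counts)
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos))
    stop("no gene has positive counts in all samples; supply a filtered ",
         "matrix or use a pseudo-reference fallback", call. = FALSE)
  lg <- log(counts[allpos, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(stats::median(col - ref)))
  sf
}

#' Normalise counts by size factors
#'
#' @param counts count matrix.
#' @param sf named size factors covering every sample.
#' @param log if TRUE, return log2(count/factor + 1).
#' @return numeric matrix, same shape as \code{counts}.
#' @export
normalize_counts <- function(counts, sf, log = FALSE) {
  validate_counts(counts)
  miss <- setdiff(colnames(counts), names(sf))
  if (length(miss) > 0)
    stop("missing size factor for sample(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  em <- sweep(counts, 2, sf[colnames(counts)], "/")
  if (log) em <- log2(em + 1)
  em
}

#' Remove additive batch effects from log-scale expression
#'
#' Fits per-gene batch-indicator coefficients under a sum-to-zero constraint
#' and subtracts them (the removeBatchEffect linear model); for balanced
#' designs the per-gene grand mean is preserved exactly. Intended for
#' visualisation and signature input, not for the count-level DE test.
#'
#' @param em expression matrix on the log scale.
#' @param batches batch label per column of \code{em}.
#' @return corrected matrix.
#' @export
remove_batch <- function(em, batches) {
  if (length(batches) != ncol(em))
    stop("one batch label per sample required", call. = FALSE)
  if (length(unique(batches)) < 2) {
    warning("single batch: returning input unchanged", call. = FALSE)
    return(em)
  }
  out <- limma::removeBatchEffect(em, batch = factor(batches))
  dimnames(out) <- dimnames(em)
  out
}

# MoM dispersion: pooled within-group variance/mean on normalised counts.
# alpha = (v - m) / m^2, floored and capped.
estimate_dispersion_mom <- function(norm, group_b, floor = 1e-8, cap = 10) {
  g1 <- norm[, !group_b, drop = FALSE]
  g2 <- norm[, group_b, drop = FALSE]
  n1 <- ncol(g1); n2 <- ncol(g2)
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- apply(g1, 1, stats::var); v2 <- apply(g2, 1, stats::var)
  # pool within-group moments weighted by degrees of freedom
  v <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  m <- (n1 * m1 + n2 * m2) / (n1 + n2)
  alpha <- (v - m) / m^2
  alpha[!is.finite(alpha)] <- floor
  pmin(pmax(alpha, floor), cap)
}

# Vectorised IRLS for the two-parameter NB GLM, log link, known dispersion.
# X = [1, x] shared by all genes; offsets log(sf). Returns beta0, beta1,
# se1, converged, deviance.
nb_irls <- function(counts, x, off, alpha, max_iter = 50, tol = 1e-8) {
  G <- nrow(counts); n <- ncol(counts)
  xr <- matrix(x, G, n, byrow = TRUE)
  offm <- matrix(off, G, n, byrow = TRUE)
  y <- counts

  # initialise from group means of offset-corrected counts
  ybar <- y / exp(offm)
  m2 <- rowMeans(ybar[, x == 1, drop = FALSE]) + 0.1
  m1 <- rowMeans(ybar[, x == 0, drop = FALSE]) + 0.1
  beta0 <- log(m1)
  beta1 <- log(m2) - log(m1)

  nb_dev <- function(mu) {
    t1 <- ifelse(y > 0, y * log(y / mu), 0)
    t2 <- (y + 1 / alpha) * log((1 + alpha * y) / (1 + alpha * mu))
    2 * rowSums(t1 - t2)
  }

  eta <- beta0 + beta1 * xr + offm
  eta <- pmin(pmax(eta, -30), 30)
  mu <- exp(eta)
  dev <- nb_dev(mu)
  converged <- rep(FALSE, G)
  A <- B <- C <- rep(NA_real_, G)

  for (it in seq_len(max_iter)) {
    w <- mu / (1 + alpha * mu)          # G x n working weights
    z <- (eta - offm) + (y - mu) / mu   # working response (linear part)
    A <- rowSums(w)
    B <- rowSums(w * xr)
    C <- rowSums(w * xr * xr)
    b1v <- rowSums(w * z)
    b2v <- rowSums(w * xr * z)
    det <- A * C - B * B
    det[det <= 0 | !is.finite(det)] <- NA
    beta0_new <- (C * b1v - B * b2v) / det
    beta1_new <- (A * b2v - B * b1v) / det
    upd <- is.finite(beta0_new) & is.finite(beta1_new) & !converged
    beta0[upd] <- beta0_new[upd]
    beta1[upd] <- beta1_new[upd]
    eta <- beta0 + beta1 * xr + offm
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    dev_new <- nb_dev(mu)
    delta <- abs(dev_new - dev) / (abs(dev) + 0.1)
    converged <- converged | (delta < tol)
    dev <- dev_new
    if (all(converged)) break
  }
  # information at the final coefficients
  w <- mu / (1 + alpha * mu)
  A <- rowSums(w); B <- rowSums(w * xr); C <- rowSums(w * xr * xr)
  se1 <- sqrt(A / (A * C - B * B))
  list(beta0 = beta0, beta1 = beta1, se1 = se1, converged = converged,
       deviance = dev)
}

#' Negative-binomial Wald differential expression test
#'
#' Contrast is given as \code{c(reference, test)}; the reported log2 fold
#' change is test over reference, so a positive value means higher expression
#' in the test group (tumour, or poor outcome). Genes with zero counts in all
#' contrast samples get an undefined p and are excluded from the BH
#' denominator.
#'
#' @param counts count matrix (all samples; the contrast subsets it).
#' @param st sample table covering the counts' samples.
#' @param contrast length-2 character: values of \code{group} (tumor/control)
#'   or \code{outcome} (poor/good), reference first.
#' @param lfc_threshold,alpha DEG thresholds: |log2FC| strictly greater than
#'   \code{lfc_threshold} and adjusted p below \code{alpha}.
#' @param dispersion_floor,dispersion_cap bounds on the MoM dispersion.
#' @return data.frame of class \code{cm_de}: gene_id, base_mean, log2fc, se,
#'   p, padj, is_deg, direction.
#' @export
nb_wald_test <- function(counts, st, contrast, lfc_threshold = 2,
                         alpha = 0.05, dispersion_floor = 1e-8,
                         dispersion_cap = 10) {
  validate_counts(counts)
  validate_sample_table(st)
  if (length(contrast) != 2) stop("contrast must have length 2", call. = FALSE)
  field <- if (all(contrast %in% c("tumor", "control"))) "group"
           else if (all(contrast %in% c("poor", "good"))) "outcome"
           else stop("contrast must name groups or outcomes", call. = FALSE)
  st <- st[match(colnames(counts), st$sample_id), ]
  sel <- st[[field]] %in% contrast
  if (sum(st[[field]] == contrast[1]) < 2 || sum(st[[field]] == contrast[2]) < 2)
    stop("both contrast groups need at least 2 samples", call. = FALSE)
  cm <- counts[, sel, drop = FALSE]
  x <- as.numeric(st[[field]][sel] == contrast[2])

  sf <- size_factors(cm)
  norm <- normalize_counts(cm, sf)
  base_mean <- rowMeans(norm)

  testable <- rowSums(cm) > 0
  res <- data.frame(gene_id = rownames(cm), base_mean = base_mean,
                    log2fc = NA_real_, se = NA_real_, p = NA_real_,
                    padj = NA_real_, is_deg = FALSE,
                    direction = NA_character_,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (any(testable)) {
    alpha_hat <- estimate_dispersion_mom(norm[testable, , drop = FALSE], x == 1,
                                         floor = dispersion_floor,
                                         cap = dispersion_cap)
    fit <- nb_irls(cm[testable, , drop = FALSE], x, log(sf), alpha_hat)
    lfc <- fit$beta1 / log(2)
    se <- fit$se1 / log(2)
    z <- fit$beta1 / fit$se1
    p <- 2 * stats::pnorm(-abs(z))
    p[!fit$converged | !is.finite(p)] <- NA
    res$log2fc[testable] <- lfc
    res$se[testable] <- se
    res$p[testable] <- p
  }
  ok <- !is.na(res$p)
  res$padj[ok] <- bh_adjust(res$p[ok])
  res$is_deg <- !is.na(res$padj) & abs(res$log2fc) > lfc_threshold &
    res$padj < alpha
  res$direction[res$is_deg] <- ifelse(res$log2fc[res$is_deg] > 0, "up", "down")
  attr(res, "contrast") <- contrast
  attr(res, "lfc_threshold") <- lfc_threshold
  attr(res, "alpha") <- alpha
  class(res) <- c("cm_de", "data.frame")
  res
}

#' Extract differentially expressed genes
#'
#' Applies the strict thresholds |log2FC| > \code{lfc_threshold} and
#' adjusted p < \code{alpha} and partitions the passing genes by direction.
#'
#' @param res result of \code{\link{nb_wald_test}}.
#' @param lfc_threshold,alpha thresholds (defaults: the study's
#'   |log2FC| > 2 and padj < 0.05).
#' @return list with \code{up}, \code{down}, and \code{all} gene id vectors.
#' @export
filter_deg <- function(res, lfc_threshold = 2, alpha = 0.05) {
  if (!all(c("log2fc", "padj") %in% names(res)))
    stop("res must contain log2fc and padj", call. = FALSE)
  pass <- !is.na(res$padj) & abs(res$log2fc) > lfc_threshold & res$padj < alpha
  up <- res$gene_id[pass & res$log2fc > 0]
  down <- res$gene_id[pass & res$log2fc < 0]
  list(up = up, down = down, all = res$gene_id[pass])
}

#' @export
print.cm_de <- function(x, ...) {
  ct <- attr(x, "contrast")
  deg <- filter_deg(x, attr(x, "lfc_threshold"), attr(x, "alpha"))
  cat("Negative-binomial Wald DE test: ", ct[2], " vs ", ct[1], "\n",
      "  genes tested: ", sum(!is.na(x$p)), " of ", nrow(x), "\n",
      "  DEG (|log2FC| > ", attr(x, "lfc_threshold"), ", padj < ",
      attr(x, "alpha"), "): ", length(deg$up), " up, ",
      length(deg$down), " down\n", sep = "")
  invisible(x)
}
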