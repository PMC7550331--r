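# The prognostic-signature engine: gene-outcome correlation ranking,
# batch-of-five stepwise selection with leave-one-out correlation-centroid
# classification, a strict-improvement AUC stopping rule, and the
# diagonal-band confident-classification geometry.
#
# Conventions fixed throughout: outcome is coded poor = 1, good = 0; the
# classification score of a sample is c_poor - c_good (correlation with the
# poor centroid minus correlation with the good centroid); the ROC positive
# class is poor; a score of exactly 0 leaves the sample unclassified.

tumor_outcome_samples <- function(em, st) {
  st <- st[match(colnames(em), st$sample_id), ]
  sel <- !is.na(st$group) & st$group == "tumor" & st$outcome %in% c("poor", "good")
  if (sum(st$outcome[sel] == "poor") < 2 || sum(st$outcome[sel] == "good") < 2)
    stop("need at least 2 tumours per outcome class", call. = FALSE)
  list(em = em[, sel, drop = FALSE], outcome = st$outcome[sel],
       ids = st$sample_id[sel])
}

#' Rank genes by absolute correlation with clinical outcome
#'
#' Point-biserial (Pearson) correlation of each gene's expression with the
#' outcome label (poor = 1, good = 0) across outcome-labelled tumours,
#' sorted by |r| descending; ties broken lexicographically by gene id.
#'
#' @param em expression matrix (typically log2 normalised counts).
#' @param st sample table; only tumours with defined outcome are used.
#' @return data.frame: gene_id, r, degenerate, rank.
#' @export
rank_by_outcome_correlation <- function(em, st) {
  d <- tumor_outcome_samples(em, st)
  y <- as.numeric(d$outcome == "poor")
  pb <- apply(d$em, 1, function(x) {
    if (stats::sd(x) == 0) c(0, 1) else c(stats::cor(x, y), 0)
  })
  res <- data.frame(gene_id = rownames(em), r = pb[1, ],
                    degenerate = pb[2, ] == 1,
                    stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(-abs(res$r), res$gene_id)
  res <- res[ord, ]
  res$rank <- seq_len(nrow(res))
  res
}

centroid_correlations <- function(profile, em_class) {
  centroid <- rowMeans(em_class)
  if (stats::sd(profile) == 0 || stats::sd(centroid) == 0) return(NA_real_)
  stats::cor(profile, centroid)
}

#' Leave-one-out correlation-centroid classification
#'
#' Each outcome-labelled tumour is held out in turn; the per-gene mean
#' profile (centroid) of the poor and good groups is recomputed without it,
#' and the held-out sample's signature-gene profile is Pearson-correlated
#' with both centroids. The classification score is c_poor - c_good; the
#' signed distance from the identity diagonal in (c_good, c_poor) space is
#' score / sqrt(2).
#'
#' @param em expression matrix.
#' @param st sample table.
#' @param genes signature gene ids (at least 2).
#' @return data.frame: sample_id, outcome, c_poor, c_good, score, distance,
#'   predicted ("poor", "good", or NA when the score ties at 0), flagged
#'   (zero-variance profile, excluded from AUC).
#' @export
loo_centroid_classify <- function(em, st, genes) {
  if (length(genes) < 2) stop("need at least 2 signature genes", call. = FALSE)
  miss <- setdiff(genes, rownames(em))
  if (length(miss) > 0)
    stop("signature gene(s) absent from expression matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  d <- tumor_outcome_samples(em[genes, , drop = FALSE], st)
  n <- ncol(d$em)
  rec <- data.frame(sample_id = d$ids, outcome = d$outcome,
                    c_poor = NA_real_, c_good = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  for (i in seq_len(n)) {
    poor_rest <- d$em[, -i, drop = FALSE][, d$outcome[-i] == "poor", drop = FALSE]
    good_rest <- d$em[, -i, drop = FALSE][, d$outcome[-i] == "good", drop = FALSE]
    rec$c_poor[i] <- centroid_correlations(d$em[, i], poor_rest)
    rec$c_good[i] <- centroid_correlations(d$em[, i], good_rest)
  }
  rec$flagged <- !is.finite(rec$c_poor) | !is.finite(rec$c_good)
  rec$score <- rec$c_poor - rec$c_good
  rec$distance <- rec$score / sqrt(2)
  rec$predicted <- ifelse(rec$flagged | rec$score == 0, NA_character_,
                          ifelse(rec$score > 0, "poor", "good"))
  rec[, c("sample_id", "outcome", "c_poor", "c_good", "score", "distance",
          "predicted", "flagged")]
}

loo_auc <- function(em, st, genes) {
  rec <- loo_centroid_classify(em, st, genes)
  ok <- !rec$flagged
  roc_auc(rec$score[ok], rec$outcome[ok] == "poor")
}

# Stop rule: k advances in steps of `batch` while the AUC strictly improves;
# an AUC of 1 stops immediately (no further improvement is possible).
choose_k <- function(auc_trace, batch) {
  ks <- as.integer(names(auc_trace))
  best <- ks[1]
  for (j in seq_along(ks)) {
    if (j == 1 || auc_trace[j] > auc_trace[j - 1]) best <- ks[j] else break
    if (auc_trace[j] >= 1) break
  }
  best
}

#' Fit a prognostic gene signature
#'
#' The model of this package: candidate genes (typically the DEG between
#' poor and good outcome) are ranked by absolute correlation with outcome;
#' genes are added in batches of \code{batch} in rank order, each candidate
#' signature is evaluated by the leave-one-out correlation-centroid
#' classifier, and growth stops as soon as the LOO ROC AUC stops strictly
#' improving (immediately at AUC = 1). The confident-classification band is
#' the sample standard deviation of the signed diagonal distances.
#'
#' @param em expression matrix (log2 normalised counts by default upstream).
#' @param st sample table.
#' @param candidates candidate gene ids; at least \code{batch} of them.
#' @param batch step size of the stepwise selection.
#' @param k_max largest signature size considered.
#' @return object of class \code{cm_signature}: \code{ranking} (all
#'   candidates with r and rank), \code{genes} (selected), \code{k},
#'   \code{auc_trace}, \code{auc}, \code{records} (LOO classification),
#'   \code{sigma} (diagonal band half-width), \code{call}.
#' @export
select_signature <- function(em, st, candidates, batch = 5, k_max = 50) {
  candidates <- unique(candidates)
  if (length(candidates) < batch)
    stop("need at least ", batch, " candidate genes", call. = FALSE)
  ranking <- rank_by_outcome_correlation(em[candidates, , drop = FALSE], st)
  ks <- seq(batch, min(k_max, nrow(ranking)), by = batch)
  auc_trace <- numeric(0)
  for (k in ks) {
    genes_k <- ranking$gene_id[seq_len(k)]
    auc_k <- loo_auc(em, st, genes_k)
    auc_trace[as.character(k)] <- auc_k
    j <- length(auc_trace)
    if (auc_k >= 1) break
    if (j > 1 && auc_trace[j] <= auc_trace[j - 1]) break
  }
  k_final <- choose_k(auc_trace, batch)
  genes <- ranking$gene_id[seq_len(k_final)]
  records <- loo_centroid_classify(em, st, genes)
  band <- decision_band(records)
  out <- list(ranking = ranking, genes = genes, k = k_final,
              auc_trace = auc_trace,
              auc = unname(auc_trace[as.character(k_final)]),
              records = band$records, sigma = band$sigma,
              batch = batch, k_max = k_max, call = match.call())
  class(out) <- "cm_signature"
  out
}

#' Diagonal decision band
#'
#' The half-width sigma of the confident-classification band around the
#' identity diagonal of the (c_good, c_poor) plane: the sample standard
#' deviation of the signed (default) or absolute distances of all samples
#' from the diagonal. A sample is confidently classified when its |distance|
#' strictly exceeds sigma.
#'
#' @param records classification records from
#'   \code{\link{loo_centroid_classify}}.
#' @param absolute use absolute instead of signed distances for sigma.
#' @return list with \code{sigma} and \code{records} (confident flag added).
#' @export
decision_band <- function(records, absolute = FALSE) {
  if (nrow(records) < 2) stop("need at least 2 records", call. = FALSE)
  d <- records$distance
  sigma <- if (absolute) stats::sd(abs(d)) else stats::sd(d)
  records$confident <- !is.na(records$predicted) & abs(d) > sigma
  list(sigma = sigma, records = records)
}

#' Export the signature heatmap matrix
#'
#' Rows are the signature genes ordered by their correlation with poor
#' outcome (highest first); columns are the outcome-labelled tumours ordered
#' by classification score (most poor-like first); values are row z-scores
#' of the supplied expression.
#'
#' @param em expression matrix.
#' @param st sample table.
#' @param model fitted \code{cm_signature}.
#' @return list with \code{matrix} (z-scores), \code{gene_order},
#'   \code{sample_order}, \code{gene_r}, \code{sample_score}.
#' @export
export_signature_heatmap <- function(em, st, model) {
  stopifnot(inherits(model, "cm_signature"))
  sig <- model$ranking[model$ranking$gene_id %in% model$genes, ]
  gene_order <- sig$gene_id[order(-sig$r, sig$gene_id)]
  rec <- model$records
  sample_order <- rec$sample_id[order(-rec$score, rec$sample_id)]
  z <- zscore_rows(em[model$genes, , drop = FALSE])[gene_order, sample_order]
  list(matrix = z, gene_order = gene_order, sample_order = sample_order,
       gene_r = stats::setNames(sig$r, sig$gene_id)[gene_order],
       sample_score = stats::setNames(rec$score, rec$sample_id)[sample_order])
}

# ---- S3 methods -----------------------------------------------------------

#' @export
print.cm_signature <- function(x, ...) {
  cat("Prognostic correlation-centroid signature\n",
      "  signature size k: ", x$k, " (batch ", x$batch, ", k_max ", x$k_max,
      ")\n  leave-one-out AUC: ", format(x$auc, digits = 4),
      "\n  AUC trace: ",
      paste(names(x$auc_trace), format(x$auc_trace, digits = 3),
            sep = ":", collapse = "  "),
      "\n  diagonal band sigma: ", format(x$sigma, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.cm_signature <- function(object, ...) {
  structure(list(k = object$k, auc = object$auc, sigma = object$sigma,
                 auc_trace = object$auc_trace,
                 genes = object$ranking[object$ranking$gene_id %in% object$genes, ],
                 records = object$records),
            class = "summary.cm_signature")
}

#' @export
print.summary.cm_signature <- function(x, ...) {
  cat("Signature of", x$k, "genes; LOO AUC", format(x$auc, digits = 4),
      "; band sigma", format(x$sigma, digits = 4), "\n\nGenes:\n")
  print(x$genes, row.names = FALSE)
  cat("\nLeave-one-out classification:\n")
  print(x$records, row.names = FALSE)
  invisible(x)
}

#' @export
coef.cm_signature <- function(object, ...) {
  sig <- object$ranking[object$ranking$gene_id %in% object$genes, ]
  stats::setNames(sig$r, sig$gene_id)
}

#' Classify samples with a fitted signature
#'
#' New samples are correlated with the poor and good centroids computed from
#' all outcome-labelled training tumours (no leave-one-out for new data).
#'
#' @param object fitted \code{cm_signature}.
#' @param em training expression matrix (defines the centroids).
#' @param st training sample table.
#' @param newdata expression matrix of samples to classify (genes in rows,
#'   must contain the signature genes). Defaults to the LOO records.
#' @param ... unused.
#' @return data.frame of classification records.
#' @export
predict.cm_signature <- function(object, em, st, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$records)
  d <- tumor_outcome_samples(em[object$genes, , drop = FALSE], st)
  poor_centroid <- rowMeans(d$em[, d$outcome == "poor", drop = FALSE])
  good_centroid <- rowMeans(d$em[, d$outcome == "good", drop = FALSE])
  profiles <- newdata[object$genes, , drop = FALSE]
  c_poor <- apply(profiles, 2, function(p)
    if (stats::sd(p) == 0) NA_real_ else stats::cor(p, poor_centroid))
  c_good <- apply(profiles, 2, function(p)
    if (stats::sd(p) == 0) NA_real_ else stats::cor(p, good_centroid))
  score <- c_poor - c_good
  data.frame(sample_id = colnames(profiles), c_poor = c_poor, c_good = c_good,
             score = score, distance = score / sqrt(2),
             predicted = ifelse(!is.finite(score) | score == 0, NA_character_,
                                ifelse(score > 0, "poor", "good")),
             confident = !is.na(score) & abs(score / sqrt(2)) > object$sigma,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Plot the classification geometry of a fitted signature
#'
#' Scatter of c_poor against c_good per tumour with the identity diagonal
#' and the +/- sigma confident-classification band.
#'
#' @param x fitted \code{cm_signature}.
#' @param ... passed to \code{plot}.
#' @export
plot.cm_signature <- function(x, ...) {
  rec <- x$records
  graphics::plot(rec$c_good, rec$c_poor, xlim = c(-1, 1), ylim = c(-1, 1),
                 xlab = "correlation with good centroid",
                 ylab = "correlation with poor centroid",
                 pch = ifelse(rec$outcome == "poor", 17, 16),
                 col = ifelse(rec$outcome == "poor", "firebrick", "orange"),
                 ...)
  graphics::abline(0, 1, lty = 2)
  off <- x$sigma * sqrt(2)
  graphics::abline(off, 1, lty = 3)
  graphics::abline(-off, 1, lty = 3)
  invisible(x)
}
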