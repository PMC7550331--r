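# Basic gene-level transformations shared by all pipeline stages.

#' Remove unexpressed and unidentifiable genes
#'
#' Drops genes whose total raw count is zero and, when annotation is
#' supplied, genes lacking a stable database identifier. Gene order is
#' preserved; the operation is idempotent.
#'
#' @param counts count matrix (genes x samples).
#' @param ann optional annotation data.frame (see \code{\link{read_annotation}});
#'   every gene in \code{counts} must be annotated.
#' @return the filtered count matrix.
#' @export
filter_genes <- function(counts, ann = NULL) {
  validate_counts(counts)
  keep <- rowSums(counts) > 0
  if (!is.null(ann)) {
    miss <- setdiff(rownames(counts), ann$gene_id)
    if (length(miss) > 0)
      stop("gene(s) missing from annotation: ", paste(miss, collapse = ", "),
           call. = FALSE)
    has_id <- ann$has_identifier[match(rownames(counts), ann$gene_id)]
    keep <- keep & has_id
  }
  counts[keep, , drop = FALSE]
}

#' Transcripts per million
#'
#' Length-normalised relative expression: per sample, each gene's count is
#' divided by its feature length, and the resulting rates are scaled to sum
#' to one million. Columns of all-zero counts stay all-zero.
#'
#' @param counts count matrix.
#' @param ann annotation with positive \code{length} per gene.
#' @return numeric matrix of TPM values, same shape as \code{counts}.
#' @export
tpm <- function(counts, ann) {
  validate_counts(counts)
  miss <- setdiff(rownames(counts), ann$gene_id)
  if (length(miss) > 0)
    stop("gene(s) missing from annotation: ", paste(miss, collapse = ", "),
         call. = FALSE)
  len <- ann$length[match(rownames(counts), ann$gene_id)]
  if (any(!is.finite(len) | len <= 0))
    stop("zero or invalid feature length for gene(s): ",
         paste(rownames(counts)[!is.finite(len) | len <= 0], collapse = ", "),
         call. = FALSE)
  rate <- counts / len
  tot <- colSums(rate)
  tot[tot == 0] <- 1  # all-zero column maps to zeros, not NaN
  sweep(rate, 2, tot, "/") * 1e6
}

#' Row-wise z-scores
#'
#' Centres each row at its mean and scales by its sample (n-1) standard
#' deviation. Constant rows map to all-zero rows rather than NaN so exported
#' heatmap matrices are always finite.
#'
#' @param em expression matrix with at least two columns.
#' @return matrix of the same shape.
#' @export
zscore_rows <- function(em) {
  if (!is.matrix(em) || ncol(em) < 2)
    stop("zscore_rows needs a matrix with at least 2 samples", call. = FALSE)
  mu <- rowMeans(em)
  sdev <- apply(em, 1, stats::sd)
  centred <- em - mu
  sdev[sdev == 0] <- Inf  # constant row -> zeros
  centred / sdev
}
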