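# Tumour-microenvironment analytics on cell-type enrichment score matrices
# (e.g. xCell output): per-type group comparisons with quotient-of-means
# fold changes, composite immune/stroma scores, and the four clinical
# subgroup contrasts.

contrast_columns <- function(st, contrast) {
  if (all(contrast %in% c("tumor", "control"))) field <- "group"
  else if (all(contrast %in% c("poor", "good"))) field <- "outcome"
  else stop("contrast must name groups or outcomes", call. = FALSE)
  list(a = st$sample_id[st[[field]] == contrast[1]],
       b = st$sample_id[st[[field]] == contrast[2]])
}

#' Compare cell-type enrichment between two groups
#'
#' Per cell type: Mann-Whitney U test between the groups and the log2 of
#' the quotient of group mean scores (undefined, NA, when either mean is
#' zero — no epsilon is injected). Rows are ordered significant-first by
#' fold change descending, ties by cell-type id.
#'
#' @param emx enrichment matrix (cell types x samples, scores in [0,1]).
#' @param st sample table.
#' @param contrast length-2 character, group A first: the reported fold
#'   change is log2(mean A / mean B).
#' @param sig_alpha significance threshold (two-sided, unadjusted, matching
#'   the p < 0.05 convention of enrichment heatmaps); a BH-adjusted column
#'   is emitted as well.
#' @return data.frame: cell_type, mean_a, mean_b, log2fc, U, p, padj,
#'   significant, direction.
#' @export
compare_cell_types <- function(emx, st, contrast = c("tumor", "control"),
                               sig_alpha = 0.05) {
  validate_sample_table(st)
  cc <- contrast_columns(st, contrast)
  a_cols <- intersect(colnames(emx), cc$a)
  b_cols <- intersect(colnames(emx), cc$b)
  if (length(a_cols) == 0 || length(b_cols) == 0)
    stop("empty contrast group", call. = FALSE)
  res <- lapply(rownames(emx), function(ct) {
    a <- emx[ct, a_cols]; b <- emx[ct, b_cols]
    mw <- mwu_exact(a, b)
    ma <- mean(a); mb <- mean(b)
    lfc <- if (ma == 0 || mb == 0) NA_real_ else log2(ma / mb)
    data.frame(cell_type = ct, mean_a = ma, mean_b = mb, log2fc = lfc,
               U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$padj <- bh_adjust(res$p)
  res$significant <- res$p < sig_alpha
  res$direction <- ifelse(is.na(res$log2fc), NA_character_,
                          ifelse(res$log2fc > 0, "up", "down"))
  ord <- order(-res$significant, -ifelse(is.na(res$log2fc), -Inf, res$log2fc),
               res$cell_type)
  res <- res[ord, ]
  rownames(res) <- NULL
  attr(res, "contrast") <- contrast
  res
}

#' Composite immune and stroma scores
#'
#' Per-sample composite of the member cell types of each category
#' (arithmetic mean by default, sum optionally). If the matrix already
#' carries precomputed composite rows, pass their row names via
#' \code{passthrough} to use them verbatim instead.
#'
#' @param emx enrichment matrix.
#' @param grouping data.frame with columns \code{cell_type} and
#'   \code{category} (immune / stroma / other) covering the matrix rows.
#' @param fun "mean" or "sum".
#' @param passthrough optional named character vector, e.g.
#'   \code{c(immune = "ImmuneScore", stroma = "StromaScore")}, naming
#'   precomputed composite rows to pass through.
#' @return data.frame: sample_id, immune, stroma.
#' @export
composite_scores <- function(emx, grouping, fun = c("mean", "sum"),
                             passthrough = NULL) {
  fun <- match.arg(fun)
  agg <- if (fun == "mean") colMeans else colSums
  one <- function(cat) {
    if (!is.null(passthrough) && cat %in% names(passthrough)) {
      row <- passthrough[[cat]]
      if (!row %in% rownames(emx))
        stop("pass-through row '", row, "' not in matrix", call. = FALSE)
      return(emx[row, ])
    }
    members <- grouping$cell_type[grouping$category == cat]
    members <- intersect(members, rownames(emx))
    if (length(members) == 0) stop("no ", cat, " cell types", call. = FALSE)
    agg(emx[members, , drop = FALSE])
  }
  data.frame(sample_id = colnames(emx), immune = one("immune"),
             stroma = one("stroma"), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Subgroup comparisons of composite scores
#'
#' Mann-Whitney comparisons of immune and stroma composite scores for the
#' four clinical contrasts: tumour vs control, poor vs good outcome,
#' recurrence vs none (within tumours), metastasis vs others (within
#' tumours). Contrasts with an empty side are skipped with a warning.
#'
#' @param emx enrichment matrix.
#' @param st sample table.
#' @param grouping cell-type category table (see
#'   \code{\link{composite_scores}}).
#' @return data.frame: contrast, score, n_a, n_b, mean_a, sd_a, mean_b,
#'   sd_b, U, p, exact.
#' @export
subgroup_score_tests <- function(emx, st, grouping) {
  validate_sample_table(st)
  comp <- composite_scores(emx, grouping)
  comp <- comp[match(colnames(emx), comp$sample_id), ]
  st <- st[match(colnames(emx), st$sample_id), ]
  tum <- !is.na(st$group) & st$group == "tumor"
  defs <- list(
    tumor_vs_control = list(a = tum, b = !tum & st$group == "control"),
    poor_vs_good = list(a = tum & st$outcome == "poor",
                        b = tum & st$outcome == "good"),
    recurrence_vs_none = list(a = tum & !is.na(st$recurrence) & st$recurrence,
                              b = tum & !is.na(st$recurrence) & !st$recurrence),
    metastasis_vs_others = list(a = tum & !is.na(st$metastasis) & st$metastasis,
                                b = tum & !is.na(st$metastasis) & !st$metastasis))
  rows <- list()
  for (cn in names(defs)) {
    sel <- defs[[cn]]
    if (!any(sel$a) || !any(sel$b)) {
      warning("contrast ", cn, " has an empty side; skipped", call. = FALSE)
      next
    }
    for (sc in c("immune", "stroma")) {
      a <- comp[[sc]][sel$a]; b <- comp[[sc]][sel$b]
      mw <- mwu_exact(a, b)
      rows[[paste(cn, sc)]] <- data.frame(
        contrast = cn, score = sc, n_a = length(a), n_b = length(b),
        mean_a = mean(a), sd_a = stats::sd(a), mean_b = mean(b),
        sd_b = stats::sd(b), U = mw$U, p = mw$p, exact = mw$exact,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
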