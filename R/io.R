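# ---- internal TSV helpers -------------------------------------------------
# Dialect: UTF-8, tab-separated, '.' decimal, no quoting; lines starting with
# '#' are provenance comments and skipped on read.

read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

write_tsv_raw <- function(df, path, provenance = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(paste0("# ", names(provenance), "=", unlist(provenance)), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

matrix_to_df <- function(m, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE, row.names = NULL)
  names(df) <- c(id_col, colnames(m))
  df
}

df_to_matrix <- function(df, id_col, path = "<data>") {
  if (names(df)[1] != id_col) {
    stop("malformed header in ", path, ": first column must be '", id_col,
         "', found '", names(df)[1], "'", call. = FALSE)
  }
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate ", id_col, " in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(df)[-1])) {
    stop("duplicate sample ids in ", path, call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  m
}

# ---- count matrices -------------------------------------------------------

#' Validate a raw count matrix
#'
#' A count matrix is a plain numeric matrix, genes in rows and samples in
#' columns, with unique row and column names and non-negative integral cells.
#'
#' @param counts matrix to validate.
#' @return the matrix, invisibly, if valid; otherwise an error.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene row names and sample column names", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in counts", call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in counts", call. = FALSE)
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("invalid count at gene '", rownames(counts)[bad[1, 1]],
         "', sample '", colnames(counts)[bad[1, 2]],
         "': counts must be non-negative integers", call. = FALSE)
  }
  invisible(counts)
}

#' Read a gene-level count matrix from TSV
#'
#' Expects a header row of sample ids with first cell \code{gene_id}, one row
#' per gene, integer cells. Row and column order are preserved.
#'
#' @param path path to a tab-separated file.
#' @return numeric matrix, genes x samples.
#' @export
read_counts <- function(path) {
  df <- read_tsv_raw(path)
  m <- df_to_matrix(df, "gene_id", path)
  storage.mode(m) <- "double"
  validate_counts(m)
  m
}

#' Write a count matrix to TSV
#'
#' @param counts validated count matrix.
#' @param path output path.
#' @param provenance optional named list written as \code{# key=value} comments.
#' @export
write_counts <- function(counts, path, provenance = NULL) {
  validate_counts(counts)
  write_tsv_raw(matrix_to_df(counts, "gene_id"), path, provenance)
}

# ---- expression / enrichment matrices -------------------------------------

#' Read a real-valued expression matrix from TSV
#'
#' @param path path; first header cell must be \code{gene_id}.
#' @return numeric matrix with finite values.
#' @export
read_expression <- function(path) {
  m <- df_to_matrix(read_tsv_raw(path), "gene_id", path)
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("non-finite expression value in ", path, call. = FALSE)
  m
}

#' @rdname read_expression
#' @param em expression matrix.
#' @param provenance optional named list of provenance comments.
#' @export
write_expression <- function(em, path, provenance = NULL) {
  write_tsv_raw(matrix_to_df(em, "gene_id"), path, provenance)
}

#' Read a cell-type enrichment score matrix
#'
#' Cell types in rows (first header cell \code{cell_type}), samples in
#' columns; scores must lie in [0, 1] as produced by signature-based
#' deconvolution tools such as xCell.
#'
#' @param path path to TSV.
#' @return numeric matrix, cell types x samples.
#' @export
read_enrichment <- function(path) {
  m <- df_to_matrix(read_tsv_raw(path), "cell_type", path)
  storage.mode(m) <- "double"
  bad <- which(!is.finite(m) | m < 0 | m > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("enrichment score outside [0,1] at cell type '",
         rownames(m)[bad[1, 1]], "', sample '", colnames(m)[bad[1, 2]], "'",
         call. = FALSE)
  }
  m
}

#' @rdname read_enrichment
#' @param emx enrichment matrix.
#' @param provenance optional provenance comments.
#' @export
write_enrichment <- function(emx, path, provenance = NULL) {
  stopifnot(is.matrix(emx), all(emx >= 0 & emx <= 1))
  write_tsv_raw(matrix_to_df(emx, "cell_type"), path, provenance)
}

# ---- sample metadata ------------------------------------------------------

#' Validate a sample table
#'
#' Required columns: \code{sample_id}, \code{group} (tumor/control),
#' \code{outcome} (poor/good/none), \code{recurrence}, \code{metastasis}
#' (logical, tumors only), \code{batch}. Controls must carry outcome
#' \code{none}; tumors must carry \code{poor} or \code{good}.
#'
#' @param st data.frame to validate.
#' @return the table, invisibly.
#' @export
validate_sample_table <- function(st) {
  req <- c("sample_id", "group", "outcome", "recurrence", "metastasis", "batch")
  miss <- setdiff(req, names(st))
  if (length(miss) > 0)
    stop("sample table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(st$sample_id))
    stop("duplicate sample_id in sample table", call. = FALSE)
  if (!all(st$group %in% c("tumor", "control")))
    stop("group must be 'tumor' or 'control'", call. = FALSE)
  if (!all(st$outcome %in% c("poor", "good", "none")))
    stop("unknown outcome label: ",
         paste(setdiff(st$outcome, c("poor", "good", "none")), collapse = ", "),
         call. = FALSE)
  bad <- (st$group == "control" & st$outcome != "none") |
         (st$group == "tumor" & st$outcome == "none")
  if (any(bad))
    stop("outcome must be poor/good for tumors and none for controls; ",
         "offending sample(s): ", paste(st$sample_id[bad], collapse = ", "),
         call. = FALSE)
  for (fl in c("recurrence", "metastasis")) {
    v <- st[[fl]]
    if (any(st$group == "control" & !is.na(v) & v))
      stop(fl, " flag set for a control sample", call. = FALSE)
  }
  invisible(st)
}

#' Read sample metadata from TSV
#'
#' @param path TSV with columns sample_id, group, outcome, recurrence,
#'   metastasis, batch.
#' @return validated data.frame.
#' @export
read_metadata <- function(path) {
  st <- read_tsv_raw(path)
  for (fl in c("recurrence", "metastasis")) {
    if (fl %in% names(st)) st[[fl]] <- as.logical(st[[fl]])
  }
  st$sample_id <- as.character(st$sample_id)
  validate_sample_table(st)
  st
}

#' @rdname read_metadata
#' @param st validated sample table.
#' @param provenance optional provenance comments.
#' @export
write_metadata <- function(st, path, provenance = NULL) {
  validate_sample_table(st)
  write_tsv_raw(st, path, provenance)
}

# ---- gene annotation ------------------------------------------------------

#' Read gene annotation from TSV
#'
#' Columns: \code{gene_id}, \code{symbol}, \code{has_identifier} (whether the
#' gene maps to a stable database identifier, e.g. an Entrez id), and
#' \code{length} (feature length in bases, > 0).
#'
#' @param path TSV path.
#' @return data.frame with one row per gene.
#' @export
read_annotation <- function(path) {
  ann <- read_tsv_raw(path)
  req <- c("gene_id", "symbol", "has_identifier", "length")
  miss <- setdiff(req, names(ann))
  if (length(miss) > 0)
    stop("annotation missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  ann$gene_id <- as.character(ann$gene_id)
  ann$has_identifier <- as.logical(ann$has_identifier)
  if (anyDuplicated(ann$gene_id)) stop("duplicate gene_id in annotation", call. = FALSE)
  if (any(!is.finite(ann$length) | ann$length <= 0))
    stop("annotation lengths must be positive", call. = FALSE)
  ann
}

#' @rdname read_annotation
#' @param ann annotation data.frame.
#' @export
write_annotation <- function(ann, path, provenance = NULL) {
  write_tsv_raw(ann, path, provenance)
}

# ---- gene sets (GMT) ------------------------------------------------------

#' Read a gene-set collection in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields
#' \code{set_id<TAB>description<TAB>member1<TAB>member2...}.
#'
#' @param path path to a GMT file.
#' @return named list; each element has \code{description} and \code{genes}.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line with no members: ", f[1], call. = FALSE)
    list(description = f[2], genes = unique(f[-(1:2)]))
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  if (anyDuplicated(names(sets))) stop("duplicate set ids in GMT", call. = FALSE)
  sets
}

#' @rdname read_gmt
#' @param sets gene-set collection as returned by \code{read_gmt}.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    paste(c(id, sets[[id]]$description, sets[[id]]$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
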