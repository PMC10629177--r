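#' Construct and validate an expression matrix
#'
#' The canonical in-memory container for expression data is a plain numeric
#' matrix with cells in rows and genes in columns, with unique row names
#' (cell identifiers) and column names (gene identifiers) and class
#' `"expr_matrix"`. Entries may be counts, CPM, TPM, FPKM or RPKM — the
#' pipeline is unit-agnostic — but must be finite and non-negative.
#'
#' @param values numeric matrix, cells x genes.
#' @param cell_ids optional character vector of cell identifiers; defaults to
#'   existing row names or `cell_1..cell_n`.
#' @param gene_ids optional character vector of gene identifiers; defaults to
#'   existing column names or `gene_1..gene_m`.
#' @return A validated `expr_matrix`.
#' @examples
#' x <- expression_matrix(matrix(0:5, 2, 3))
#' dim(x)
#' @export
expression_matrix <- function(values, cell_ids = NULL, gene_ids = NULL) {
  check_that(is.matrix(values) && is.numeric(values),
             "`values` must be a numeric matrix")
  if (is.null(cell_ids)) cell_ids <- rownames(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- colnames(values)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(values)))
  dimnames(values) <- list(as.character(cell_ids), as.character(gene_ids))
  class(values) <- c("expr_matrix", class(matrix()))
  validate_expression_matrix(values)
}

#' @rdname expression_matrix
#' @param x object to validate / test.
#' @export
validate_expression_matrix <- function(x) {
  check_that(nrow(x) >= 2, "an expression matrix needs at least 2 cells")
  check_that(!anyNA(x), "missing values (NA) are not allowed: scRNA-seq zeros are zeros, not NA")
  check_that(all(is.finite(x)), "all entries must be finite")
  check_that(min(x) >= 0, "negative expression values are not allowed")
  check_that(!anyDuplicated(rownames(x)), "duplicate cell identifiers")
  check_that(!anyDuplicated(colnames(x)), "duplicate gene identifiers")
  x
}

#' @rdname expression_matrix
#' @export
is_expression_matrix <- function(x) inherits(x, "expr_matrix")

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d cells x %d genes\n", nrow(x), ncol(x)))
  invisible(x)
}

# sniff "," vs tab from the header line
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) >=
      lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
}

#' Read an expression matrix from disk
#'
#' Supports dense delimited text (CSV or TSV auto-detected from the header
#' line, first column holding identifiers) and Matrix Market triplet files
#' with companion gene/barcode lists as written by 10x-style pipelines.
#' Whatever the on-disk layout, the returned matrix is cells x genes.
#'
#' @param path path to the matrix file.
#' @param orientation `"cells_by_genes"` (default for delimited files) or
#'   `"genes_by_cells"`. For Matrix Market input the default follows the 10x
#'   ecosystem convention of genes x cells on disk.
#' @param format `"auto"` (by file extension), `"delimited"` or
#'   `"matrix_market"`.
#' @param genes_file,barcodes_file companions for Matrix Market input; when
#'   `NULL`, `genes.tsv`/`features.tsv` and `barcodes.tsv` next to `path` are
#'   tried.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path,
                                   orientation = NULL,
                                   format = c("auto", "delimited", "matrix_market"),
                                   genes_file = NULL, barcodes_file = NULL) {
  format <- match.arg(format)
  check_that(file.exists(path), sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "matrix_market" else "delimited"
  }
  if (format == "delimited") {
    orientation <- match.arg(orientation %||% "cells_by_genes",
                             c("cells_by_genes", "genes_by_cells"))
    sep <- detect_sep(path)
    df <- tryCatch(
      read.table(path, header = TRUE, sep = sep, row.names = 1,
                 check.names = FALSE, comment.char = "",
                 stringsAsFactors = FALSE),
      error = function(e) stop(sprintf("parse error in %s: %s", path, conditionMessage(e)),
                               call. = FALSE))
    m <- as.matrix(df)
    if (!is.numeric(m)) {
      bad <- which(!vapply(df, is.numeric, logical(1)))[1]
      stop(sprintf("non-numeric value in column '%s' of %s", names(df)[bad], path),
           call. = FALSE)
    }
    if (orientation == "genes_by_cells") m <- t(m)
  } else {
    orientation <- match.arg(orientation %||% "genes_by_cells",
                             c("cells_by_genes", "genes_by_cells"))
    mm <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    if (is.null(genes_file)) {
      for (cand in file.path(dir, c("genes.tsv", "features.tsv"))) {
        if (file.exists(cand)) { genes_file <- cand; break }
      }
    }
    if (is.null(barcodes_file)) {
      cand <- file.path(dir, "barcodes.tsv")
      if (file.exists(cand)) barcodes_file <- cand
    }
    read_ids <- function(f, n, what) {
      if (is.null(f)) return(paste0(what, "_", seq_len(n)))
      ids <- read.table(f, header = FALSE, sep = "\t",
                        stringsAsFactors = FALSE)[[1]]
      check_that(length(ids) == n,
                 sprintf("%s list %s has %d entries, matrix has %d", what, f,
                         length(ids), n))
      ids
    }
    if (orientation == "genes_by_cells") {
      rownames(mm) <- read_ids(genes_file, nrow(mm), "gene")
      colnames(mm) <- read_ids(barcodes_file, ncol(mm), "cell")
      m <- t(mm)
    } else {
      rownames(mm) <- read_ids(barcodes_file, nrow(mm), "cell")
      colnames(mm) <- read_ids(genes_file, ncol(mm), "gene")
      m <- mm
    }
  }
  expression_matrix(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Drop genes expressed in too few cells
#'
#' The 10x preprocessing rule: a gene is kept only if its expression is
#' strictly positive in at least `min_cells` cells. Cell set and gene order
#' are preserved.
#'
#' @param x an [expression_matrix()].
#' @param min_cells minimum number of expressing cells (default 3).
#' @return The filtered `expr_matrix`.
#' @export
filter_low_prevalence_genes <- function(x, min_cells = 3) {
  x <- validate_expression_matrix(x)
  check_that(is.numeric(min_cells) && min_cells >= 1, "`min_cells` must be >= 1")
  keep <- colSums(x > 0) >= min_cells
  if (!any(keep)) {
    stop(sprintf(paste0("all %d genes are expressed in fewer than %d cells; ",
                        "lower `min_cells`"), ncol(x), min_cells), call. = FALSE)
  }
  expression_matrix(unclass(x)[, keep, drop = FALSE])
}

#' Read a label file
#'
#' Accepts one-column files (labels in input order) or two-column files
#' (cell_id, label); a header is detected and skipped when its first field is
#' `cell_id`.
#'
#' @param path label file.
#' @return Character vector of labels, named by cell id when available.
#' @export
read_labels <- function(path) {
  check_that(file.exists(path), sprintf("file not found: %s", path))
  sep <- detect_sep(path)
  df <- read.table(path, header = FALSE, sep = sep, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (nrow(df) > 0 && df[1, 1] %in% c("cell_id", "cell", "barcode")) df <- df[-1, , drop = FALSE]
  if (ncol(df) >= 2) stats::setNames(df[[2]], df[[1]]) else df[[1]]
}

#' Write / read clustering assignments
#'
#' Assignments go to disk as two-column tab-delimited text
#' (`cell_id`, `cluster`) with a header; `read_result` returns the label
#' vector named by cell id.
#'
#' @param result a `clustering_result` (see [agglomerative_from_similarity()])
#'   or a named label vector.
#' @param path output path.
#' @export
write_result <- function(result, path) {
  labels <- if (inherits(result, "clustering_result")) result$labels else result
  ids <- names(labels) %||% paste0("cell_", seq_along(labels))
  df <- data.frame(cell_id = ids, cluster = unname(labels))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(df$cluster, df$cell_id)
}

#' Write / read a square similarity matrix
#'
#' Delimited with a `cell_id` leading column and cell ids as header; values
#' are written with full double precision so that a write/read round trip is
#' an identity to ~1e-15 relative error.
#'
#' @param m square numeric matrix with cell-id dimnames.
#' @param path file path.
#' @export
write_matrix <- function(m, path) {
  check_that(is.matrix(m) && nrow(m) == ncol(m), "`m` must be a square matrix")
  ids <- rownames(m) %||% paste0("cell_", seq_len(nrow(m)))
  header <- paste(c("cell_id", ids), collapse = ",")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(ids[i], formatC(m[i, ], format = "g", digits = 17)), collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = detect_sep(path), row.names = 1,
                   check.names = FALSE, comment.char = "")
  as.matrix(df)
}

#' Export per-cell vectors (a similarity matrix row block or an LSTM
#' embedding) for external visualisation tools such as t-SNE/UMAP
#'
#' @param embedding numeric matrix, one row per cell.
#' @param path output path (CSV, `cell_id` first column).
#' @export
export_embedding <- function(embedding, path) {
  ids <- rownames(embedding) %||% paste0("cell_", seq_len(nrow(embedding)))
  df <- data.frame(cell_id = ids, embedding, check.names = FALSE)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
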