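#' Labeled count matrix
#'
#' The package's central container: a sparse genes x cells matrix of unique
#' read (UMI) counts together with per-cell labels (group, batch) and per-gene
#' annotations (mitochondrial flag, marker class). Orientation follows the
#' CellRanger convention of features in rows and barcodes in columns.
#'
#' @param counts sparse (or dense, coerced) numeric matrix of non-negative
#'   integer counts, genes in rows, cells in columns. Row names are gene
#'   identifiers, column names cell barcodes; both are required.
#' @param cell_info data.frame with one row per cell. Must contain a `group`
#'   column; a `batch` column is added (single batch) when absent. Extra
#'   columns are carried along untouched.
#' @param gene_info data.frame with one row per gene, or `NULL` to derive a
#'   minimal annotation. A logical `mito` column flags mitochondrial genes
#'   (default: feature names with the `mt-` prefix, case-insensitive).
#' @param mito_prefix feature-name prefix used to flag mitochondrial genes
#'   when `gene_info` does not already carry a `mito` column.
#'
#' @return An object of class `labeled_counts`: a list with elements
#'   `counts` (dgCMatrix), `cell_info`, `gene_info`.
#' @export
#' @examples
#' m <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 2), x = c(3, 1), dims = c(2, 2))
#' dimnames(m) <- list(c("Gene1", "mt-Nd1"), c("AAAC-1", "AAAG-1"))
#' lc <- labeled_counts(m, data.frame(group = c("stellate", "P1")))
#' lc$gene_info$mito
labeled_counts <- function(counts, cell_info, gene_info = NULL,
                           mito_prefix = "mt-") {
  dn <- dimnames(counts)
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  dimnames(counts) <- dn
  ## an empty dimension legitimately has no names (Matrix normalizes
  ## character(0) to NULL)
  if ((is.null(rownames(counts)) && nrow(counts) > 0L) ||
      (is.null(colnames(counts)) && ncol(counts) > 0L)) {
    stop("`counts` must have gene row names and cell barcode column names",
         call. = FALSE)
  }
  barcodes <- colnames(counts) %||% character(0)
  gene_ids_in <- rownames(counts) %||% character(0)
  x <- counts@x
  if (any(x < 0) || any(x != floor(x))) {
    stop("`counts` must contain non-negative integers", call. = FALSE)
  }
  if (anyDuplicated(barcodes)) {
    stop("cell barcodes must be unique", call. = FALSE)
  }

  cell_info <- as.data.frame(cell_info, stringsAsFactors = FALSE)
  if (nrow(cell_info) != ncol(counts)) {
    stop(sprintf("`cell_info` has %d rows but `counts` has %d cells",
                 nrow(cell_info), ncol(counts)), call. = FALSE)
  }
  if (is.null(cell_info$group)) {
    stop("`cell_info` must contain a `group` column", call. = FALSE)
  }
  if (is.null(cell_info$batch)) cell_info$batch <- "batch1"
  cell_info$barcode <- barcodes
  rownames(cell_info) <- barcodes

  if (is.null(gene_info)) {
    gene_info <- data.frame(gene_id = gene_ids_in,
                            stringsAsFactors = FALSE)
  } else {
    gene_info <- as.data.frame(gene_info, stringsAsFactors = FALSE)
    if (nrow(gene_info) != nrow(counts)) {
      stop("`gene_info` must have one row per gene", call. = FALSE)
    }
    gene_info$gene_id <- gene_ids_in
  }
  if (is.null(gene_info$mito)) {
    gene_info$mito <- startsWith(tolower(gene_info$gene_id),
                                 tolower(mito_prefix))
  }
  rownames(gene_info) <- gene_ids_in

  structure(list(counts = counts, cell_info = cell_info,
                 gene_info = gene_info),
            class = "labeled_counts")
}

#' @export
dim.labeled_counts <- function(x) dim(x$counts)

#' @export
print.labeled_counts <- function(x, ...) {
  cat(sprintf("<labeled_counts> %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  grp <- table(x$cell_info$group)
  cat("groups:", paste(sprintf("%s (%d)", names(grp), grp), collapse = ", "),
      "\n")
  cat(sprintf("mitochondrial genes flagged: %d\n", sum(x$gene_info$mito)))
  invisible(x)
}

#' Subset a labeled count matrix by cells
#'
#' @param x a `labeled_counts` object.
#' @param cells logical, integer, or barcode character vector of cells to keep.
#' @return a `labeled_counts` with the selected cells, gene set unchanged.
#' @export
subset_cells <- function(x, cells) {
  stopifnot(inherits(x, "labeled_counts"))
  labeled_counts(x$counts[, cells, drop = FALSE],
                 x$cell_info[cells, setdiff(names(x$cell_info), "barcode"),
                             drop = FALSE],
                 x$gene_info)
}
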