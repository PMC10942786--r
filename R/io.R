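## CellRanger-style Matrix Market triplet I/O.
##
## Layout: matrix.mtx(.gz) + features.tsv(.gz) + barcodes.tsv(.gz) in one
## directory, optionally with a labels.tsv sidecar (barcode, group, batch;
## tab-separated, header required).

locate_triplet_file <- function(dir, stem) {
  for (cand in c(stem, paste0(stem, ".gz"))) {
    p <- file.path(dir, cand)
    if (file.exists(p)) return(p)
  }
  stop(sprintf("missing file: %s(.gz) not found in %s", stem, dir),
       call. = FALSE)
}

read_tsv_maybe_gz <- function(path, header = FALSE) {
  con <- if (endsWith(path, ".gz")) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  read.delim(con, header = header, stringsAsFactors = FALSE)
}

#' Read a CellRanger-style filtered feature-barcode matrix
#'
#' Loads a Matrix Market triplet (`matrix.mtx`, `features.tsv`,
#' `barcodes.tsv`, each optionally gzip-compressed) and attaches per-cell
#' group/batch labels, either from a `labels.tsv` sidecar in the same
#' directory (columns `barcode`, `group`, `batch`; header required) or from a
#' constant sample label.
#'
#' @param path directory holding the triplet.
#' @param labels path to a label sidecar table, or `NULL` to use
#'   `path/labels.tsv` when present.
#' @param sample_label single group label applied to every cell when no label
#'   table is available.
#' @param mito_prefix passed to [labeled_counts()].
#' @return a [labeled_counts] object.
#' @export
read_cellranger_mtx <- function(path, labels = NULL, sample_label = NULL,
                                mito_prefix = "mt-") {
  if (!dir.exists(path)) {
    stop(sprintf("directory not found: %s", path), call. = FALSE)
  }
  mtx_path <- locate_triplet_file(path, "matrix.mtx")
  feat_path <- locate_triplet_file(path, "features.tsv")
  bc_path <- locate_triplet_file(path, "barcodes.tsv")

  m <- if (endsWith(mtx_path, ".gz")) {
    Matrix::readMM(gzfile(mtx_path))
  } else {
    Matrix::readMM(mtx_path)
  }
  features <- read_tsv_maybe_gz(feat_path)
  barcodes <- read_tsv_maybe_gz(bc_path)

  if (nrow(features) != nrow(m)) {
    stop(sprintf("dimension mismatch: %s lists %d features but %s has %d rows",
                 basename(feat_path), nrow(features), basename(mtx_path),
                 nrow(m)), call. = FALSE)
  }
  if (nrow(barcodes) != ncol(m)) {
    stop(sprintf("dimension mismatch: %s lists %d barcodes but %s has %d columns",
                 basename(bc_path), nrow(barcodes), basename(mtx_path),
                 ncol(m)), call. = FALSE)
  }
  vals <- m@x
  if (any(vals < 0) || any(vals != floor(vals))) {
    stop(sprintf("non-integer or negative values in %s", basename(mtx_path)),
         call. = FALSE)
  }
  ## CellRanger features.tsv: id, name[, type]; gene symbol preferred when
  ## present, falling back to the id column.
  gene_ids <- if (ncol(features) >= 2) features[[2]] else features[[1]]
  gene_ids <- make.unique(as.character(gene_ids))
  rownames(m) <- gene_ids
  colnames(m) <- as.character(barcodes[[1]])

  if (is.null(labels)) {
    default_sidecar <- file.path(path, "labels.tsv")
    if (file.exists(default_sidecar)) labels <- default_sidecar
  }
  if (!is.null(labels)) {
    lab <- read.delim(labels, header = TRUE, stringsAsFactors = FALSE)
    need <- c("barcode", "group")
    if (!all(need %in% names(lab))) {
      stop(sprintf("label table %s must have columns barcode, group", labels),
           call. = FALSE)
    }
    idx <- match(colnames(m), lab$barcode)
    if (anyNA(idx)) {
      stop(sprintf("label table %s is missing %d barcodes (e.g. %s)", labels,
                   sum(is.na(idx)), colnames(m)[which(is.na(idx))[1]]),
           call. = FALSE)
    }
    cell_info <- lab[idx, setdiff(names(lab), "barcode"), drop = FALSE]
  } else if (!is.null(sample_label)) {
    cell_info <- data.frame(group = rep(sample_label, ncol(m)),
                            stringsAsFactors = FALSE)
  } else {
    stop("no labels.tsv sidecar found; supply `labels` or `sample_label`",
         call. = FALSE)
  }

  labeled_counts(m, cell_info, mito_prefix = mito_prefix)
}

#' Write a labeled count matrix as a CellRanger-style triplet
#'
#' Writes `matrix.mtx`, `features.tsv`, `barcodes.tsv` and a `labels.tsv`
#' sidecar (barcode, group, batch) into `path`. With `gzip = TRUE` the triplet
#' files are gzip-compressed as in CellRanger output.
#'
#' @param x a [labeled_counts] object.
#' @param path output directory, created if needed.
#' @param gzip compress the triplet files?
#' @return `path`, invisibly.
#' @export
write_cellranger_mtx <- function(x, path, gzip = FALSE) {
  stopifnot(inherits(x, "labeled_counts"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)

  mtx <- file.path(path, "matrix.mtx")
  Matrix::writeMM(x$counts, mtx)
  feat <- data.frame(id = x$gene_info$gene_id, name = x$gene_info$gene_id,
                     type = "Gene Expression")
  write.table(feat, file.path(path, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(x$counts), file.path(path, "barcodes.tsv"))
  if (gzip) {
    for (stem in c("matrix.mtx", "features.tsv", "barcodes.tsv")) {
      f <- file.path(path, stem)
      gz <- paste0(f, ".gz")
      con_in <- file(f, "rb"); con_out <- gzfile(gz, "wb")
      writeBin(readBin(con_in, "raw", file.size(f)), con_out)
      close(con_in); close(con_out)
      unlink(f)
    }
  }
  lab <- data.frame(barcode = colnames(x$counts),
                    group = x$cell_info$group,
                    batch = x$cell_info$batch)
  write.table(lab, file.path(path, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
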