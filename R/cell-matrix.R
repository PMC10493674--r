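#' Single-cell expression container
#'
#' A light-weight genes x cells container used throughout the pipeline:
#' a (sparse) count and/or normalized value matrix plus per-cell metadata
#' (`sample`, `disease`, `sex`, `region`, and after processing `cluster`,
#' `cell_type`) and per-gene metadata (`mito` flag).
#'
#' @param counts genes x cells matrix of non-negative integer counts
#'   (base matrix or `Matrix::dgCMatrix`), with rownames (gene ids) and
#'   colnames (cell ids).
#' @param cell_meta data.frame with one row per cell; columns `sample`,
#'   `disease`, `sex`, `region` (missing ones are filled with `"unknown"`).
#' @param gene_meta data.frame with one row per gene; logical column `mito`.
#'   If omitted, mitochondrial genes are flagged by symbol prefix.
#' @param values optional genes x cells matrix of normalized values.
#' @param mito_prefix regular expression applied to gene ids to flag
#'   mitochondrial genes when `gene_meta` is absent (default `"^MT-|^mt-"`).
#' @return An object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, cell_meta, gene_meta = NULL, values = NULL,
                        mito_prefix = "^MT-|^mt-") {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must carry gene ids (rownames) and cell ids (colnames)")
  if (nrow(cell_meta) == 1 && ncol(counts) > 1)   # recycle shared labels
    cell_meta <- cell_meta[rep(1, ncol(counts)), , drop = FALSE]
  if (nrow(cell_meta) != ncol(counts))
    stopf("cell_meta has %d rows for %d cells", nrow(cell_meta), ncol(counts))
  for (col in c("sample", "disease", "sex", "region"))
    if (is.null(cell_meta[[col]])) cell_meta[[col]] <- "unknown"
  if (is.null(gene_meta))
    gene_meta <- data.frame(mito = grepl(mito_prefix, rownames(counts)))
  if (nrow(gene_meta) != nrow(counts))
    stopf("gene_meta has %d rows for %d genes", nrow(gene_meta), nrow(counts))
  rownames(cell_meta) <- colnames(counts)
  rownames(gene_meta) <- rownames(counts)
  structure(list(counts = counts, values = values,
                 cell_meta = cell_meta, gene_meta = gene_meta),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix: %d genes x %d cells (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$values)) "raw counts" else "normalized"))
  if (!is.null(x$cell_meta$cell_type))
    print(table(x$cell_meta$cell_type))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

gene_ids <- function(m) rownames(m$counts)
cell_ids <- function(m) colnames(m$counts)

# Subset cells, keeping counts/values/metadata in register.
subset_cells <- function(m, idx) {
  m$counts <- m$counts[, idx, drop = FALSE]
  if (!is.null(m$values)) m$values <- m$values[, idx, drop = FALSE]
  m$cell_meta <- m$cell_meta[idx, , drop = FALSE]
  m
}

#' Write / read a single-cell dataset as MatrixMarket + TSV
#'
#' Writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and `metadata.tsv`
#' into `dir` (10x-style layout); `read_sc_dataset()` round-trips it.
#'
#' @param m a [cell_matrix()] holding raw counts.
#' @param dir output/input directory.
#' @return `write_sc_dataset()` returns `dir` invisibly; `read_sc_dataset()`
#'   returns a [cell_matrix()].
#' @export
write_sc_dataset <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(methods::as(m$counts, "dMatrix"), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(gene_ids(m), file.path(dir, "genes.tsv"))
  writeLines(cell_ids(m), file.path(dir, "barcodes.tsv"))
  write.table(cbind(cell_id = cell_ids(m), m$cell_meta),
              file.path(dir, "metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_sc_dataset
#' @export
read_sc_dataset <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  rownames(counts) <- readLines(file.path(dir, "genes.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  meta <- read.delim(file.path(dir, "metadata.tsv"), stringsAsFactors = FALSE)
  meta$cell_id <- NULL
  cell_matrix(counts, meta)
}
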