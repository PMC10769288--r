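#' Cell-by-gene count matrix with per-cell metadata
#'
#' Lightweight container for an integer cells x genes count matrix plus a
#' per-cell metadata table. Rows are cells, columns are genes; `cell_meta` is
#' keyed by `cell_id` and may carry spatial coordinates (`x_um`, `y_um`),
#' segmented `volume`, blank-barcode counts (`blanks`), `sample` and
#' `condition` columns, and any label columns.
#'
#' @param counts integer matrix, cells x genes, with unique dimnames.
#' @param cell_meta data.frame with a `cell_id` column covering every cell, or
#'   `NULL` for a minimal one.
#' @return An object of class `count_matrix` with elements `counts`,
#'   `gene_ids`, `cell_ids`, `cell_meta`.
#' @export
count_matrix <- function(counts, cell_meta = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("cell%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("gene%04d", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("count_matrix: duplicate cell or gene ids")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("count_matrix: counts must be finite and non-negative")
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(cell_id = rownames(counts),
                            stringsAsFactors = FALSE)
  }
  if (!"cell_id" %in% names(cell_meta))
    stop("count_matrix: cell_meta needs a cell_id column")
  if (!all(rownames(counts) %in% cell_meta$cell_id))
    stop("count_matrix: cell_meta does not cover every cell")
  cell_meta <- cell_meta[match(rownames(counts), cell_meta$cell_id), ,
                         drop = FALSE]
  rownames(cell_meta) <- NULL
  structure(list(counts = counts,
                 gene_ids = colnames(counts),
                 cell_ids = rownames(counts),
                 cell_meta = cell_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  cat("meta columns:", paste(names(x$cell_meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by cells and/or genes
#'
#' @param x a `count_matrix`.
#' @param cells,genes logical/integer/character index vectors (default: keep
#'   all). Cell order is preserved for logical indices.
#' @return A `count_matrix`.
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(cells)) cells <- seq_len(nrow(x$counts))
  if (is.null(genes)) genes <- seq_len(ncol(x$counts))
  cm <- x$counts[cells, genes, drop = FALSE]
  meta <- x$cell_meta[match(rownames(cm), x$cell_meta$cell_id), , drop = FALSE]
  count_matrix(cm, meta)
}

#' Write a count matrix to disk (MatrixMarket or CSV)
#'
#' `mtx` writes `matrix.mtx` (genes in columns), `genes.tsv`, `cells.tsv` and
#' `cell_meta.csv` into `dir`; `csv` writes a dense `counts.csv` plus the
#' metadata table.
#'
#' @param x a `count_matrix`.
#' @param dir output directory (created if missing).
#' @param format `"mtx"` or `"csv"`.
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(x, dir, format = c("mtx", "csv")) {
  stopifnot(inherits(x, "count_matrix"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE),
                    file.path(dir, "matrix.mtx"))
    writeLines(x$gene_ids, file.path(dir, "genes.tsv"))
    writeLines(x$cell_ids, file.path(dir, "cells.tsv"))
  } else {
    utils::write.csv(x$counts, file.path(dir, "counts.csv"))
  }
  utils::write.csv(x$cell_meta, file.path(dir, "cell_meta.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param dir directory containing the files.
#' @param format `"mtx"` or `"csv"`.
#' @return A `count_matrix`.
#' @export
read_count_matrix <- function(dir, format = c("mtx", "csv")) {
  format <- match.arg(format)
  meta <- utils::read.csv(file.path(dir, "cell_meta.csv"),
                          stringsAsFactors = FALSE)
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
    rownames(m) <- readLines(file.path(dir, "cells.tsv"))
    colnames(m) <- readLines(file.path(dir, "genes.tsv"))
  } else {
    m <- as.matrix(utils::read.csv(file.path(dir, "counts.csv"),
                                   row.names = 1, check.names = FALSE))
  }
  count_matrix(m, meta)
}

#' Normalized expression container
#'
#' Holds the two layers downstream stages need: `lognorm`, the non-negative
#' size- and log-normalized values (log10(x + 1)), and `z`, the per-gene
#' z-scored layer used for PCA / archetypes / ABC scores. `provenance` records
#' the ordered transforms applied; `excluded_genes` the genes omitted from
#' size-factor computation.
#'
#' @param lognorm,z numeric cells x genes matrices (same dimnames).
#' @param provenance character vector of transform descriptions (non-empty).
#' @param excluded_genes character vector (possibly empty).
#' @param cell_meta per-cell metadata carried along.
#' @return An object of class `normalized_matrix`.
#' @export
normalized_matrix <- function(lognorm, z, provenance, excluded_genes = character(),
                              cell_meta = NULL) {
  stopifnot(identical(dim(lognorm), dim(z)), length(provenance) >= 1)
  structure(list(lognorm = lognorm, z = z, values = z,
                 provenance = provenance, excluded_genes = excluded_genes,
                 cell_meta = cell_meta),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d cells x %d genes\n",
              nrow(x$z), ncol(x$z)))
  cat("provenance:\n")
  for (p in x$provenance) cat("  -", p, "\n")
  invisible(x)
}
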