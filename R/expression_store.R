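#' Build an expression store from a matrix and cell-type annotations
#'
#' The store is a [SingleCellExperiment::SingleCellExperiment] with genes as
#' rows, cells as columns, a `counts` assay and a `cell_type` column in
#' `colData`. Cells without a usable annotation (absent from the table, `NA`,
#' `"NA"` or empty label) are dropped with a message: annotation is an input
#' contract, not something to impute.
#'
#' @param counts genes x cells matrix (dense or `Matrix` sparse), with
#'   rownames = gene identifiers and colnames = cell identifiers.
#' @param cell_types named character vector or factor mapping cell id to
#'   cell-type label, or an unnamed vector aligned with `colnames(counts)`.
#' @return A `SingleCellExperiment`.
#' @export
expression_store <- function(counts, cell_types) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and cell colnames")
  vals <- if (methods::is(counts, "sparseMatrix")) counts@x else counts
  if (any(!is.finite(vals))) stop("expression values must be finite")
  if (min(counts) < 0) stop("expression values must be non-negative")
  ct <- as.character(cell_types)
  if (!is.null(names(cell_types))) {
    ct <- ct[match(colnames(counts), names(cell_types))]
  } else if (length(ct) != ncol(counts)) {
    stop("cell_types length (", length(ct), ") != number of cells (",
         ncol(counts), ")")
  }
  bad <- is.na(ct) | ct == "" | ct == "NA"
  if (all(bad)) stop("no annotated cells")
  if (any(bad)) {
    message("dropping ", sum(bad), " cell(s) without cell-type annotation")
    counts <- counts[, !bad, drop = FALSE]
    ct <- ct[!bad]
  }
  SingleCellExperiment(assays = list(counts = methods::as(counts, "CsparseMatrix")),
                       colData = DataFrame(cell_type = ct,
                                           row.names = colnames(counts)))
}

#' Read an expression matrix plus annotation from files
#'
#' Supports sparse MatrixMarket triplet files (`.mtx`, with one-column gene and
#' cell identifier files) and dense delimited text (TSV/CSV with a header row
#' of gene symbols and a first column of cell identifiers). MTX files follow
#' the common genes-as-rows convention by default; `orientation =
#' "cells-as-rows"` transposes on load. The annotation file is two-column
#' (cell_id, cell_type), tab- or comma-separated, with or without a header.
#'
#' @param matrix_path path to `.mtx` or dense delimited matrix.
#' @param annotation_path path to the cell-type annotation table.
#' @param genes_path,cells_path identifier files, required for MTX input.
#' @param orientation matrix orientation on file, MTX input only.
#' @return A `SingleCellExperiment` (see [expression_store()]).
#' @export
read_expression <- function(matrix_path, annotation_path,
                            genes_path = NULL, cells_path = NULL,
                            orientation = c("genes-as-rows", "cells-as-rows")) {
  orientation <- match.arg(orientation)
  for (p in c(matrix_path, annotation_path, genes_path, cells_path))
    if (!file.exists(p)) stop("cannot read file: ", p)
  if (grepl("\\.mtx$", matrix_path, ignore.case = TRUE)) {
    if (is.null(genes_path) || is.null(cells_path))
      stop("MTX input needs genes_path and cells_path identifier files")
    m <- methods::as(readMM(matrix_path), "CsparseMatrix")
    genes <- readLines(genes_path, warn = FALSE)
    cells <- readLines(cells_path, warn = FALSE)
    if (orientation == "cells-as-rows") m <- Matrix::t(m)
    if (nrow(m) != length(genes))
      stop("genes file length (", length(genes), ") != matrix gene dimension (",
           nrow(m), ")")
    if (ncol(m) != length(cells))
      stop("cells file length (", length(cells), ") != matrix cell dimension (",
           ncol(m), ")")
    dimnames(m) <- list(genes, cells)
  } else {
    sep <- if (grepl("\\.csv$", matrix_path, ignore.case = TRUE)) "," else "\t"
    d <- read.delim(matrix_path, sep = sep, header = TRUE, row.names = 1L,
                    check.names = FALSE)
    # dense layout is cells x genes: header = gene symbols, first column = cell ids
    m <- methods::as(Matrix::t(as.matrix(d)), "CsparseMatrix")
  }
  ann <- read_annotation(annotation_path)
  expression_store(m, cell_types = ann)
}

read_annotation <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl(",", first) && !grepl("\t", first)) "," else "\t"
  header <- grepl("cell", tolower(first))
  d <- read.delim(path, sep = sep, header = header,
                  colClasses = "character")
  if (ncol(d) < 2L) stop("annotation must have two columns: cell_id, cell_type")
  stats::setNames(d[[2L]], d[[1L]])
}

#' Counts-per-million normalization
#'
#' Rescales every cell so its values sum to one million, removing library-size
#' (sequencing-depth) differences that would otherwise inflate apparent
#' expression variability. Cells with zero total counts are dropped with a
#' message. The result replaces the `counts` assay with a `cpm` assay;
#' downstream functions use the `cpm` assay when present.
#'
#' @param store a `SingleCellExperiment` with a `counts` assay.
#' @param assay_name assay holding the raw values (default `"counts"`).
#' @return The store with a `cpm` assay.
#' @export
normalize_cpm <- function(store, assay_name = "counts") {
  m <- assay(store, assay_name)
  tot <- colSums(m)
  if (all(tot == 0)) stop("all cells have zero total counts")
  if (any(tot == 0)) {
    message("dropping ", sum(tot == 0), " cell(s) with zero total counts")
    store <- store[, tot > 0]
    m <- assay(store, assay_name)
    tot <- tot[tot > 0]
  }
  cpm <- m %*% Diagonal(x = 1e6 / tot)
  dimnames(cpm) <- dimnames(m)
  assay(store, "cpm", withDimnames = FALSE) <- cpm
  store
}

values_assay <- function(store) {
  if ("cpm" %in% assayNames(store)) assay(store, "cpm") else assay(store, "counts")
}

#' Mean expression per cell type
#'
#' Arithmetic mean of each gene over the cells of each annotated type, the
#' precomputation behind the specificity matrix. Cell types with fewer than
#' `min_cells` cells are dropped with a message.
#'
#' @param store a `SingleCellExperiment` with `cell_type` annotation; the `cpm`
#'   assay is used when present, else `counts`.
#' @param min_cells minimum cells for a type to be retained (default 10; use 1
#'   to keep everything).
#' @return An object of class `celltype_means`: list with `means` (cell types x
#'   genes matrix) and `n_cells` (named integer).
#' @export
celltype_means <- function(store, min_cells = 10L) {
  ct <- factor(colData(store)$cell_type)
  n <- table(ct)
  keep <- names(n)[n >= min_cells]
  if (length(keep) == 0L)
    stop("no cell type has >= ", min_cells, " cells")
  if (length(keep) < nlevels(ct))
    message("dropping ", nlevels(ct) - length(keep),
            " cell type(s) with < ", min_cells, " cells")
  m <- values_assay(store)
  ind <- sparseMatrix(i = seq_along(ct)[ct %in% keep],
                      j = as.integer(factor(as.character(ct[ct %in% keep]), levels = keep)),
                      x = 1, dims = c(length(ct), length(keep)))
  n_kept <- as.integer(n[keep])
  means <- Matrix::t(m %*% ind %*% Diagonal(x = 1 / n_kept))
  means <- as.matrix(means)
  dimnames(means) <- list(keep, rownames(store))
  structure(list(means = means,
                 n_cells = stats::setNames(n_kept, keep)),
            class = "celltype_means")
}

#' @export
print.celltype_means <- function(x, ...) {
  cat("celltype_means: ", nrow(x$means), " cell types x ", ncol(x$means),
      " genes\n", sep = "")
  invisible(x)
}
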