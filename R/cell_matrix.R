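#' Gene-by-cell expression container
#'
#' A `CellMatrix` holds UMI counts (genes x cells), an optional
#' log10-normalized layer, and per-cell annotations (patient, clone id).
#' Matrix orientation is fixed as genes x cells throughout the package to
#' avoid silent transposes.
#'
#' @param counts non-negative integer matrix or sparse `dgCMatrix`
#'   (genes x cells), with gene ids as rownames and cell barcodes as colnames.
#' @param cell_meta data.frame with one row per cell: columns `barcode`,
#'   `patient`, and optionally `clone_id` (NA for cells without recovered
#'   TCR; such cells stay in the matrix but are excluded from clone-level
#'   operations).
#' @param lognorm optional matrix of log10-normalized values, same shape as
#'   `counts`. Usually produced by [normalize_log()].
#'
#' @return an object of class `CellMatrix`: a list with elements `counts`,
#'   `lognorm` (possibly `NULL`) and `cell_meta`.
#' @export
CellMatrix <- function(counts, cell_meta, lognorm = NULL) {
  if (!inherits(counts, "Matrix")) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (any(counts@x != round(counts@x))) stop("counts must be integral")
  bc <- colnames(counts)
  if (is.null(bc) || anyDuplicated(bc))
    stop("cell barcodes (colnames) must be present and unique")
  if (is.null(rownames(counts))) stop("gene ids (rownames) must be present")
  cell_meta <- as.data.frame(cell_meta)
  if (!all(c("barcode", "patient") %in% names(cell_meta)))
    stop("cell_meta needs columns 'barcode' and 'patient'")
  if (!setequal(cell_meta$barcode, bc))
    stop("cell_meta barcodes do not match matrix columns")
  cell_meta <- cell_meta[match(bc, cell_meta$barcode), , drop = FALSE]
  rownames(cell_meta) <- NULL
  if (!"clone_id" %in% names(cell_meta)) cell_meta$clone_id <- NA_character_
  if (!is.null(lognorm)) {
    if (!identical(dim(lognorm), dim(counts)))
      stop("lognorm must have the same shape as counts")
  }
  structure(list(counts = counts, lognorm = lognorm, cell_meta = cell_meta),
            class = "CellMatrix")
}

#' @export
print.CellMatrix <- function(x, ...) {
  cat(sprintf("CellMatrix: %d genes x %d cells (%d patients, %d clones)%s\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$patient)),
              length(unique(stats::na.omit(x$cell_meta$clone_id))),
              if (is.null(x$lognorm)) ", raw counts only" else ", log-normalized"))
  invisible(x)
}

#' @export
dim.CellMatrix <- function(x) dim(x$counts)

#' Load a 10x-style MTX triplet
#'
#' Reads a MatrixMarket coordinate file plus gene and barcode TSVs into a
#' [CellMatrix()]. The genes file may have one or more columns; the first is
#' used as the gene id. Patient ids default to a single placeholder and can
#' be attached later via `cell_meta`.
#'
#' @param matrix_path path to the `.mtx` file (genes x cells).
#' @param genes_path path to a TSV of gene ids (no header).
#' @param barcodes_path path to a TSV of cell barcodes (no header).
#' @param cell_meta optional data.frame as in [CellMatrix()]; defaults to a
#'   single unknown patient.
#' @return a [CellMatrix()] with the counts layer populated and no lognorm
#'   layer (call [normalize_log()]).
#' @export
load_expression <- function(matrix_path, genes_path, barcodes_path,
                            cell_meta = NULL) {
  for (p in c(matrix_path, genes_path, barcodes_path))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- Matrix::readMM(matrix_path)
  genes <- utils::read.delim(genes_path, header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  barcodes <- utils::read.delim(barcodes_path, header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(genes))
    stop(sprintf("matrix has %d rows but genes file has %d entries",
                 nrow(m), length(genes)))
  if (ncol(m) != length(barcodes))
    stop(sprintf("matrix has %d columns but barcodes file has %d entries",
                 ncol(m), length(barcodes)))
  if (anyDuplicated(barcodes)) stop("duplicate barcodes in barcodes file")
  dimnames(m) <- list(genes, barcodes)
  if (is.null(cell_meta))
    cell_meta <- data.frame(barcode = barcodes, patient = "unknown",
                            stringsAsFactors = FALSE)
  CellMatrix(m, cell_meta)
}

#' Write a CellMatrix counts layer as an MTX triplet
#'
#' @param cm a [CellMatrix()].
#' @param dir output directory (created if missing); writes `matrix.mtx`,
#'   `genes.tsv`, `barcodes.tsv`.
#' @return invisibly, the directory.
#' @export
write_expression <- function(cm, dir) {
  stopifnot(inherits(cm, "CellMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(cm$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(cm$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(cm$counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Log10 depth normalization
#'
#' Computes `lognorm[g, c] = log10(1 + scale * counts[g, c] / colsum(c))`.
#' Cells with zero total counts become all-zero columns. The default scale
#' of 10,000 follows the 10x community convention; the log base is 10.
#'
#' @param cm a [CellMatrix()] with counts.
#' @param scale positive scale factor (default 1e4).
#' @return the CellMatrix with the `lognorm` layer filled in.
#' @export
normalize_log <- function(cm, scale = 1e4) {
  stopifnot(inherits(cm, "CellMatrix"), scale > 0)
  cs <- Matrix::colSums(cm$counts)
  div <- ifelse(cs > 0, cs, 1)
  ln <- cm$counts %*% Matrix::Diagonal(x = scale / div)
  ln <- methods::as(ln, "CsparseMatrix")
  ln@x <- log10(1 + ln@x)
  dimnames(ln) <- dimnames(cm$counts)
  cm$lognorm <- ln
  cm
}

#' Clone-average pseudo-bulk profiles
#'
#' Averages the log-normalized layer over the cells of each clone, yielding a
#' genes x clones profile matrix on which the bulk-style differential
#' expression analogues operate. Column order follows the clone table.
#'
#' @param cm a [CellMatrix()] with a lognorm layer.
#' @param ct a [CloneTable()].
#' @return dense numeric matrix, genes x clones, columns named by clone_id.
#' @export
pseudobulk_by_clone <- function(cm, ct) {
  stopifnot(inherits(cm, "CellMatrix"), inherits(ct, "CloneTable"))
  if (is.null(cm$lognorm)) stop("lognorm layer absent; call normalize_log()")
  cl <- cm$cell_meta$clone_id
  missing <- setdiff(ct$clone_id, cl)
  if (length(missing))
    stop("clones with no matched cells: ", paste(missing, collapse = ", "))
  idx <- split(seq_along(cl), cl)[ct$clone_id]
  # indicator matrix cells x clones scaled to 1/n gives the mean in one product
  j <- rep(seq_along(idx), lengths(idx))
  i <- unlist(idx, use.names = FALSE)
  w <- Matrix::sparseMatrix(i = i, j = j, x = 1 / lengths(idx)[j],
                            dims = c(ncol(cm$lognorm), length(idx)))
  prof <- as.matrix(cm$lognorm %*% w)
  dimnames(prof) <- list(rownames(cm$lognorm), ct$clone_id)
  prof
}
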