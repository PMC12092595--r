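#' Cell-by-gene count matrix
#'
#' Lightweight container for a cells x genes expression matrix. Counts are
#' nonnegative; a `layer` tag records whether values are raw integer counts
#' (`"raw"`) or log-normalized expression (`"lognorm"`). The matrix may be a
#' base dense matrix or a [Matrix::sparseMatrix()]; all package operations
#' accept either.
#'
#' @param counts cells x genes numeric matrix (base or Matrix), entries >= 0.
#' @param cell_ids unique cell identifiers; defaults to `rownames(counts)`.
#' @param gene_ids unique gene identifiers; defaults to `colnames(counts)`.
#' @param layer `"raw"` or `"lognorm"`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (dimnamed matrix) and `layer`.
#' @examples
#' m <- count_matrix(matrix(0:5, 2, 3,
#'   dimnames = list(c("c1", "c2"), c("g1", "g2", "g3"))))
#' n_cells(m)
#' @export
count_matrix <- function(counts, cell_ids = rownames(counts),
                         gene_ids = colnames(counts), layer = "raw") {
  if (!(is.matrix(counts) || is(counts, "Matrix"))) {
    stop_("`counts` must be a base matrix or a Matrix object")
  }
  if (is.null(cell_ids) || is.null(gene_ids)) {
    stop_("cell and gene identifiers are required (dimnames or arguments)")
  }
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(cell_ids)) stop_("duplicate cell identifiers")
  if (anyDuplicated(gene_ids)) stop_("duplicate gene identifiers")
  if (nrow(counts) != length(cell_ids) || ncol(counts) != length(gene_ids)) {
    stop_("matrix dimensions do not match the identifier lists")
  }
  if (length(counts) && min(counts) < 0) stop_("negative entries are not allowed")
  if (!layer %in% c("raw", "lognorm")) stop_("layer must be 'raw' or 'lognorm'")
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts, layer = layer), class = "count_matrix")
}

#' @rdname count_matrix
#' @param x a `count_matrix`.
#' @export
n_cells <- function(x) nrow(x$counts)

#' @rdname count_matrix
#' @export
n_genes <- function(x) ncol(x$counts)

#' @rdname count_matrix
#' @export
cell_ids <- function(x) rownames(x$counts)

#' @rdname count_matrix
#' @export
gene_ids <- function(x) colnames(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d genes [layer=%s, %s]\n",
              n_cells(x), n_genes(x), x$layer,
              if (is(x$counts, "sparseMatrix")) "sparse" else "dense"))
  invisible(x)
}

#' @export
as.matrix.count_matrix <- function(x, ...) as.matrix(x$counts)

dense_counts <- function(x) {
  if (is.matrix(x$counts)) x$counts else as.matrix(x$counts)
}

require_layer <- function(x, layer, fun) {
  if (!inherits(x, "count_matrix")) stop_(fun, "() expects a count_matrix")
  if (x$layer != layer) {
    stop_(fun, "() requires a '", layer, "' layer matrix, got '", x$layer, "'")
  }
  invisible(x)
}

#' Read a count matrix
#'
#' Reads either a Matrix Market triplet bundle (`matrix.mtx` + `genes.tsv` +
#' `barcodes.tsv`, genes in rows as in the usual 10x layout) or a dense CSV
#' with cells in rows, a `cell_id` first column and gene identifiers as the
#' header. The result is always cells x genes with `layer = "raw"` and
#' preserves the input row/column order.
#'
#' @param path a directory containing `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`; or a path to a `.mtx` file with those siblings; or a
#'   `.csv` file.
#' @return A [count_matrix()] with `layer = "raw"`.
#' @export
read_count_matrix <- function(path) {
  if (length(path) != 1L || !is.character(path)) stop_("`path` must be a single string")
  if (dir.exists(path)) {
    return(read_mtx_bundle(file.path(path, "matrix.mtx"),
                           file.path(path, "genes.tsv"),
                           file.path(path, "barcodes.tsv")))
  }
  if (!file.exists(path)) stop_("no such file: ", path)
  if (grepl("\\.mtx$", path)) {
    d <- dirname(path)
    return(read_mtx_bundle(path, file.path(d, "genes.tsv"),
                           file.path(d, "barcodes.tsv")))
  }
  if (grepl("\\.csv$", path)) return(read_dense_csv(path))
  stop_("unrecognised count matrix format: ", path)
}

read_mtx_bundle <- function(mtx, genes, barcodes) {
  for (f in c(mtx, genes, barcodes)) {
    if (!file.exists(f)) stop_("missing file: ", f)
  }
  m <- Matrix::readMM(mtx)                      # genes x cells
  g <- read.delim(genes, header = FALSE, stringsAsFactors = FALSE)
  b <- read.delim(barcodes, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(g) != nrow(m)) stop_("genes.tsv has ", nrow(g), " rows, matrix has ", nrow(m))
  if (nrow(b) != ncol(m)) stop_("barcodes.tsv has ", nrow(b), " rows, matrix has ", ncol(m))
  counts <- as(Matrix::t(m), "CsparseMatrix")   # cells x genes
  count_matrix(counts, cell_ids = b[[1]], gene_ids = g[[1]], layer = "raw")
}

read_dense_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_("dense CSV needs a cell_id column plus >=1 gene column")
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  count_matrix(mat, cell_ids = ids, gene_ids = colnames(df)[-1], layer = "raw")
}

#' Write a count matrix
#'
#' Inverse of [read_count_matrix()]: a `.csv` path writes the dense CSV
#' rendering, any other path is treated as a directory and receives the
#' Matrix Market triplet bundle. Integer counts round-trip bitwise.
#'
#' @param x a [count_matrix()].
#' @param path output `.csv` file or bundle directory.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  if (grepl("\\.csv$", path)) {
    df <- data.frame(cell_id = cell_ids(x), check.names = FALSE,
                     stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(dense_counts(x), check.names = FALSE))
    write.csv(df, path, row.names = FALSE)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    m <- as(as(Matrix::t(as(x$counts, "CsparseMatrix")), "generalMatrix"),
            "CsparseMatrix")
    Matrix::writeMM(m, file.path(path, "matrix.mtx"))
    writeLines(gene_ids(x), file.path(path, "genes.tsv"))
    writeLines(cell_ids(x), file.path(path, "barcodes.tsv"))
  }
  invisible(path)
}
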