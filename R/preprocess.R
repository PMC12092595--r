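#' QC thresholds for spot/cell filtering
#'
#' Defaults are the filter set used for sequencing-based spatial data:
#' min_genes = 100 detected genes per cell/spot, min counts 2000, max
#' counts 35000, and each gene detected in at least 3 cells/spots
#' ("min_spots = 3" is the gene-level rule in that parameter set).
#'
#' @param min_genes_per_cell minimum detected genes per cell.
#' @param min_cells_per_gene minimum cells a gene must be detected in.
#' @param min_counts_per_cell,max_counts_per_cell total-count window per cell.
#' @return A list of thresholds (class `qc_thresholds`).
#' @export
qc_thresholds <- function(min_genes_per_cell = 100L, min_cells_per_gene = 3L,
                          min_counts_per_cell = 2000L,
                          max_counts_per_cell = 35000L) {
  if (min_counts_per_cell > max_counts_per_cell) {
    stop_("min_counts_per_cell must be <= max_counts_per_cell")
  }
  if (min_genes_per_cell < 0 || min_cells_per_gene < 0 ||
      min_counts_per_cell < 0) {
    stop_("thresholds must be nonnegative")
  }
  structure(list(min_genes_per_cell = min_genes_per_cell,
                 min_cells_per_gene = min_cells_per_gene,
                 min_counts_per_cell = min_counts_per_cell,
                 max_counts_per_cell = max_counts_per_cell),
            class = "qc_thresholds")
}

#' Filter poor-quality cells and rarely detected genes
#'
#' Cell-level rules run first, in order (min genes detected, then the
#' total-count window); the gene-level rule (min cells per gene) is then
#' applied on the surviving cells. The report attributes each removed
#' cell/gene to the first rule it failed, so per-rule removals sum to the
#' totals removed.
#'
#' @param m a raw-layer [count_matrix()].
#' @param t a [qc_thresholds()].
#' @return List with `matrix` (filtered [count_matrix()]) and `report`
#'   (class `qc_report`).
#' @export
qc_filter <- function(m, t = qc_thresholds()) {
  require_layer(m, "raw", "qc_filter")
  stopifnot(inherits(t, "qc_thresholds"))
  counts <- m$counts
  genes_per_cell <- as.numeric(Matrix::rowSums(counts > 0))
  totals <- as.numeric(Matrix::rowSums(counts))

  fail_genes <- genes_per_cell < t$min_genes_per_cell
  fail_min <- !fail_genes & totals < t$min_counts_per_cell
  fail_max <- !fail_genes & !fail_min & totals > t$max_counts_per_cell
  keep_cells <- !(fail_genes | fail_min | fail_max)

  report <- structure(list(
    thresholds = unclass(t),
    removed = list(min_genes_per_cell = sum(fail_genes),
                   min_counts_per_cell = sum(fail_min),
                   max_counts_per_cell = sum(fail_max),
                   min_cells_per_gene = NA_integer_),
    n_cells_in = n_cells(m), n_cells_out = sum(keep_cells),
    n_genes_in = n_genes(m), n_genes_out = NA_integer_),
    class = "qc_report")

  if (!any(keep_cells)) {
    cond <- errorCondition("qc_filter removed every cell; check thresholds",
                           report = report,
                           class = c("isgt_qc_error", "error"))
    stop(cond)
  }

  sub <- counts[keep_cells, , drop = FALSE]
  cells_per_gene <- as.numeric(Matrix::colSums(sub > 0))
  keep_genes <- cells_per_gene >= t$min_cells_per_gene
  report$removed$min_cells_per_gene <- sum(!keep_genes)
  report$n_genes_out <- sum(keep_genes)

  out <- count_matrix(sub[, keep_genes, drop = FALSE], layer = "raw")
  list(matrix = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  cells: %d -> %d\n", x$n_cells_in, x$n_cells_out))
  cat(sprintf("  genes: %d -> %d\n", x$n_genes_in, x$n_genes_out))
  for (r in names(x$removed)) {
    cat(sprintf("  removed by %s: %d\n", r, x$removed[[r]]))
  }
  invisible(x)
}

#' Write a QC report as JSON
#' @param report a `qc_report`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Normalization dialect
#'
#' `"visium"`: totals scaled to 10,000 and log2-transformed with
#' pseudocount 1 (sequencing-based spatial data). `"xenium"`: totals
#' scaled to 1,000 and natural-log transformed with pseudocount 1
#' (imaging-based data, the scanpy normalize_total/log1p route).
#' `"custom"` takes the three parameters explicitly.
#'
#' @param preset `"visium"`, `"xenium"` or `"custom"`.
#' @param target_sum,log_base,pseudocount parameters for `"custom"`
#'   (`log_base` is `"2"` or `"e"`); ignored otherwise.
#' @return A list (class `norm_dialect`).
#' @export
norm_dialect <- function(preset = c("visium", "xenium", "custom"),
                         target_sum = NULL, log_base = NULL,
                         pseudocount = NULL) {
  preset <- match.arg(preset)
  d <- switch(preset,
    visium = list(target_sum = 10000, log_base = "2", pseudocount = 1),
    xenium = list(target_sum = 1000, log_base = "e", pseudocount = 1),
    custom = {
      if (is.null(target_sum) || is.null(log_base) || is.null(pseudocount)) {
        stop_("custom dialect needs target_sum, log_base and pseudocount")
      }
      list(target_sum = target_sum, log_base = as.character(log_base),
           pseudocount = pseudocount)
    })
  if (d$target_sum <= 0) stop_("target_sum must be positive")
  if (!d$log_base %in% c("2", "e")) stop_("log_base must be '2' or 'e'")
  if (d$pseudocount <= 0) stop_("pseudocount must be positive")
  d$preset <- preset
  structure(d, class = "norm_dialect")
}

#' Log-normalize a raw count matrix
#'
#' Per cell: value = log_base(count / total * target_sum + pseudocount).
#' The pseudocount is added after scaling. Cells with zero total counts are
#' an error (run [qc_filter()] first).
#'
#' @param m a raw-layer [count_matrix()].
#' @param d a [norm_dialect()].
#' @return A [count_matrix()] with `layer = "lognorm"`.
#' @export
normalize_counts <- function(m, d = norm_dialect("visium")) {
  require_layer(m, "raw", "normalize_counts")
  stopifnot(inherits(d, "norm_dialect"))
  totals <- as.numeric(Matrix::rowSums(m$counts))
  if (any(totals <= 0)) {
    bad <- cell_ids(m)[which(totals <= 0)]
    stop_("cell(s) with zero total counts cannot be normalized: ",
          paste(head(bad, 5), collapse = ", "),
          if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else "")
  }
  logdiv <- if (d$log_base == "2") log(2) else 1
  if (is(m$counts, "sparseMatrix") && d$pseudocount == 1) {
    # row-scale then log1p: zero entries stay zero, sparsity preserved
    scaled <- Matrix::Diagonal(x = d$target_sum / totals) %*% m$counts
    vals <- log1p(scaled) / logdiv
    vals <- as(vals, "CsparseMatrix")
  } else {
    dense <- dense_counts(m)
    scaled <- dense / totals * d$target_sum
    vals <- log(scaled + d$pseudocount) / logdiv
  }
  count_matrix(vals, cell_ids = cell_ids(m), gene_ids = gene_ids(m),
               layer = "lognorm")
}
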