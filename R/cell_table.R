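LINEAGE_LEVELS <- c("lymphocyte", "non_lymphocyte", "other")

#' Read a per-cell annotation table
#'
#' Reads a CSV/TSV with at least `cell_id` and `sample_id` columns
#' (typically also `condition` and `cell_type`) and fills the `lineage`
#' column from an explicit cell-type-to-lineage mapping. Lineage is never
#' inferred from names: any cell type absent from `lineage_map` becomes
#' `"other"` with one warning per distinct unmapped type.
#'
#' @param path CSV (comma) or TSV (tab) file with a header row.
#' @param lineage_map named character vector or list mapping `cell_type` to
#'   one of `"lymphocyte"`, `"non_lymphocyte"`, `"other"`. May be empty.
#' @param t_types character vector of cell types to flag as T cells
#'   (`is_T`). If `NULL`, an existing `is_T` column is kept, otherwise
#'   `is_T` is `FALSE`.
#' @return A data.frame with columns `cell_id`, `sample_id`, `condition`,
#'   `cell_type`, `lineage`, `is_T`.
#' @export
read_cell_table <- function(path, lineage_map = NULL, t_types = NULL) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  check_cols(df, c("cell_id", "sample_id"), "cell table")
  make_cell_table(df, lineage_map = lineage_map, t_types = t_types)
}

#' @rdname read_cell_table
#' @param df a data.frame already holding the cell-table columns.
#' @export
make_cell_table <- function(df, lineage_map = NULL, t_types = NULL) {
  check_cols(df, c("cell_id", "sample_id"), "cell table")
  df$cell_id <- as.character(df$cell_id)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$cell_id)) stop_("duplicated cell_id in cell table")
  if (is.null(df$condition)) df$condition <- NA_character_
  if (is.null(df$cell_type)) df$cell_type <- NA_character_
  df$lineage <- assign_lineage(df$cell_type, lineage_map)
  if (!is.null(t_types)) {
    df$is_T <- df$cell_type %in% t_types
  } else if (is.null(df$is_T)) {
    df$is_T <- FALSE
  } else {
    df$is_T <- as.logical(df$is_T)
  }
  rownames(df) <- NULL
  df
}

assign_lineage <- function(cell_type, lineage_map) {
  map <- unlist(lineage_map %||% character())
  if (length(map)) {
    bad <- setdiff(unique(map), LINEAGE_LEVELS)
    if (length(bad)) {
      stop_("invalid lineage value(s) in map: ", paste(bad, collapse = ", "),
            " (allowed: ", paste(LINEAGE_LEVELS, collapse = ", "), ")")
    }
  }
  out <- unname(map[cell_type])
  unmapped <- unique(cell_type[is.na(out) & !is.na(cell_type)])
  for (ty in unmapped) {
    warning("cell type '", ty, "' not in lineage map; assigned lineage 'other'",
            call. = FALSE)
  }
  out[is.na(out)] <- "other"
  out
}

#' Read gene sets
#'
#' Reads either a GMT file (tab-separated: set name, description, genes) or
#' a plain newline-delimited gene list (one symbol per line; the set is
#' named after the file). Within-set duplicates are dropped with a warning;
#' a set empty after deduplication is an error.
#'
#' @param path GMT or newline-list file.
#' @return A named list of character vectors (one per gene set).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop_("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_("gene set file is empty: ", path)
  if (any(grepl("\t", lines))) {
    sets <- lapply(lines, function(l) {
      f <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (length(f) < 3L) stop_("malformed GMT line (need name, description, genes)")
      list(name = f[1], genes = f[-(1:2)])
    })
    nm <- vapply(sets, `[[`, "", "name")
    genes <- lapply(sets, `[[`, "genes")
    names(genes) <- nm
  } else {
    genes <- list(trimws(lines))
    names(genes) <- sub("\\.[^.]*$", "", basename(path))
  }
  lapply(stats::setNames(names(genes), names(genes)), function(nm) {
    g <- genes[[nm]]
    g <- g[nzchar(g)]
    if (anyDuplicated(g)) {
      warning("gene set '", nm, "' contains duplicated symbols; keeping one copy",
              call. = FALSE)
      g <- unique(g)
    }
    if (!length(g)) stop_("gene set '", nm, "' is empty after deduplication")
    g
  })
}

#' Bundled minimal gene sets
#'
#' Only gene symbols named in the main text are bundled: an ISG anchor set
#' (ISG15, ISG20, IFIT1, IRF7) and a cytotoxicity anchor (GZMB). Real
#' analyses should supply the full curated signatures via
#' [read_gene_sets()]; these minimal sets exist so examples and pipelines
#' run without external files.
#'
#' @return Named list of character vectors.
#' @export
default_gene_sets <- function() {
  list(ISG = c("ISG15", "ISG20", "IFIT1", "IRF7"),
       cytotoxicity = "GZMB")
}

#' Match gene symbols against a matrix's genes
#'
#' Case-sensitive by default (human vs mouse symbol casing differs);
#' `ignore_case = TRUE` enables a case-insensitive fallback.
#'
#' @param genes query symbols.
#' @param universe gene identifiers present in the matrix.
#' @param ignore_case match case-insensitively.
#' @return The subset of `universe` matched, in query order.
#' @export
match_genes <- function(genes, universe, ignore_case = FALSE) {
  if (ignore_case) {
    idx <- match(toupper(genes), toupper(universe))
    universe[idx[!is.na(idx)]]
  } else {
    genes[genes %in% universe]
  }
}
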