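#' Assign genes to equal-frequency expression bins
#'
#' Genes are ranked by mean log-normalized expression across cells and cut
#' into `n_bins` bins of (near-)equal size; bin sizes differ by at most one,
#' with lower bins taking the extra gene. Ties in mean expression are broken
#' by gene order in the matrix, so the assignment is deterministic.
#'
#' @param m a lognorm-layer [count_matrix()].
#' @param n_bins number of bins (1 <= n_bins <= number of genes).
#' @return Named integer vector: gene id -> bin (1 = lowest expression).
#' @export
bin_genes <- function(m, n_bins = 24L) {
  require_layer(m, "lognorm", "bin_genes")
  g <- n_genes(m)
  if (n_bins < 1L) stop_("n_bins must be >= 1")
  if (n_bins > g) stop_("n_bins (", n_bins, ") exceeds the number of genes (", g, ")")
  means <- as.numeric(Matrix::colMeans(m$counts))
  ord <- order(means, seq_len(g))       # stable: ties by gene position
  sizes <- rep(g %/% n_bins, n_bins)
  extra <- g %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bins <- integer(g)
  bins[ord] <- rep(seq_len(n_bins), times = sizes)
  stats::setNames(bins, gene_ids(m))
}

#' Per-cell gene-program score with expression-matched controls
#'
#' For each cell: mean log-normalized expression of the program genes minus
#' the mean expression of a control pool. The pool is built by drawing
#' `n_ctrl_per_gene` control genes (without replacement, program genes
#' excluded) from the expression bin of each program gene and taking the
#' union; this matches the control genes to the program's expression
#' distribution so that under no program activity the score is centred at
#' zero. The draw is fixed by `seed`: with the RNG seeded, for each present
#' program gene in gene-set order, `sample()` is called on the bin's
#' candidate genes in matrix column order.
#'
#' @param m a lognorm-layer [count_matrix()] (scoring raw counts is an
#'   error, not a silent cast).
#' @param genes character vector of program gene symbols.
#' @param n_bins number of expression bins (default 24).
#' @param n_ctrl_per_gene control genes drawn per program gene (default 100);
#'   bins smaller than this are sampled with replacement with a warning.
#' @param seed RNG seed fixing the control draw.
#' @param program_name label written into the output.
#' @param ignore_case case-insensitive gene matching fallback.
#' @return data.frame `cell_id`, `program`, `score`.
#' @export
score_program <- function(m, genes, n_bins = 24L, n_ctrl_per_gene = 100L,
                          seed = 1L, program_name = "program",
                          ignore_case = FALSE) {
  require_layer(m, "lognorm", "score_program")
  if (n_ctrl_per_gene < 1L) stop_("n_ctrl_per_gene must be >= 1")
  gid <- gene_ids(m)
  present <- match_genes(genes, gid, ignore_case = ignore_case)
  if (!length(present)) {
    stop_("none of the program genes are present in the matrix")
  }
  if (length(present) < length(genes)) {
    warning(length(genes) - length(present),
            " program gene(s) absent from the matrix were dropped",
            call. = FALSE)
  }
  bins <- bin_genes(m, n_bins)
  pool <- with_seed(seed, {
    drawn <- vector("list", length(present))
    for (k in seq_along(present)) {
      gbin <- bins[[present[k]]]
      cand <- gid[bins == gbin & !(gid %in% present)]
      if (!length(cand)) {
        stop_("expression bin of gene '", present[k],
              "' has no control candidates")
      }
      replace <- length(cand) < n_ctrl_per_gene
      if (replace) {
        warning("bin of gene '", present[k], "' has ", length(cand),
                " candidates < n_ctrl_per_gene = ", n_ctrl_per_gene,
                "; sampling with replacement", call. = FALSE)
      }
      drawn[[k]] <- sample(cand, n_ctrl_per_gene, replace = replace)
    }
    unique(unlist(drawn))
  })
  prog_mean <- as.numeric(Matrix::rowMeans(m$counts[, present, drop = FALSE]))
  ctrl_mean <- as.numeric(Matrix::rowMeans(m$counts[, pool, drop = FALSE]))
  data.frame(cell_id = cell_ids(m), program = program_name,
             score = prog_mean - ctrl_mean, stringsAsFactors = FALSE)
}

parse_call_rule <- function(rule) {
  if (is.list(rule)) return(rule)
  parts <- strsplit(rule, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop_("rule must look like 'sd:3', 'quantile:0.99' or 'abs:0.5'")
  type <- parts[1]
  value <- suppressWarnings(as.numeric(parts[2]))
  if (!type %in% c("sd", "quantile", "abs") || is.na(value)) {
    stop_("unrecognised calling rule: ", rule)
  }
  list(type = type, value = value)
}

#' Call ISG-T cells from program scores
#'
#' Thresholds the per-cell program score. The default rule `"sd:3"` sets
#' the threshold at mean + 3 SD of the score over reference cells — the
#' non-T cells when any are present (cells not expected to carry the
#' program), otherwise all scored cells. `"quantile:q"` uses the q-quantile
#' of the reference scores and `"abs:x"` an absolute threshold. ISG-T
#' cells are conventionally defined by unsupervised clustering; this
#' explicit rule is the auditable substitute, and externally derived
#' cluster labels can be used instead by passing them straight to
#' [isgt_frequency()].
#'
#' @param scores output of [score_program()].
#' @param cells cell table with `cell_id` and `is_T`.
#' @param rule `"sd:k"`, `"quantile:q"` or `"abs:x"`.
#' @return data.frame `cell_id`, `is_isgt`, `rule` (threshold description).
#' @export
call_isgt <- function(scores, cells, rule = "sd:3") {
  check_cols(scores, c("cell_id", "score"), "scores")
  check_cols(cells, c("cell_id", "is_T"), "cell table")
  r <- parse_call_rule(rule)
  df <- merge(scores, cells[, c("cell_id", "is_T")], by = "cell_id",
              sort = FALSE)
  if (!nrow(df)) stop_("no scored cells overlap the cell table")
  ref <- if (any(!df$is_T)) df$score[!df$is_T] else df$score
  if (!length(ref)) stop_("empty reference set for threshold estimation")
  threshold <- switch(r$type,
    sd = mean(ref) + r$value * sd_or_zero(ref),
    quantile = as.numeric(quantile(ref, r$value)),
    abs = r$value)
  data.frame(cell_id = df$cell_id,
             is_isgt = df$score > threshold,
             rule = sprintf("%s:%g (threshold=%.6g)", r$type, r$value, threshold),
             stringsAsFactors = FALSE)
}

sd_or_zero <- function(x) if (length(x) > 1L) sd(x) else 0

#' Per-sample frequency of ISG-T cells among T cells
#'
#' @param calls output of [call_isgt()] (or any data.frame with `cell_id`
#'   and logical `is_isgt`, e.g. external cluster labels).
#' @param cells cell table with `cell_id`, `sample_id`, `is_T` (and
#'   optionally `condition`).
#' @return data.frame per sample: `sample_id`, `condition`, `n_T`,
#'   `n_isgt`, `frequency`. Samples with zero T cells get `NA` frequency,
#'   not zero.
#' @export
isgt_frequency <- function(calls, cells) {
  check_cols(calls, c("cell_id", "is_isgt"), "calls")
  check_cols(cells, c("cell_id", "sample_id", "is_T"), "cell table")
  df <- merge(cells, calls[, c("cell_id", "is_isgt")], by = "cell_id",
              all.x = TRUE, sort = FALSE)
  df$is_isgt[is.na(df$is_isgt)] <- FALSE
  samples <- unique(df$sample_id)
  out <- lapply(samples, function(s) {
    sub <- df[df$sample_id == s, , drop = FALSE]
    n_T <- sum(sub$is_T)
    n_isgt <- sum(sub$is_T & sub$is_isgt)
    data.frame(sample_id = s,
               condition = if (!is.null(sub$condition)) sub$condition[1] else NA,
               n_T = n_T, n_isgt = n_isgt,
               frequency = if (n_T > 0) n_isgt / n_T else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
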