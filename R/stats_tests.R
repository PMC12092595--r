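#' Compare nearest-focal distances between conditions
#'
#' Groups the per-cell distances of one cell type by condition and applies
#' the requested test: `"anova_tukey"` (one-way ANOVA F test plus all
#' pairwise Tukey HSD adjusted p-values, the multi-group default),
#' `"mann_whitney"`/`"wilcoxon"` (the two-sided rank-sum test, two groups)
#' or `"welch_t"` (Welch two-tailed t, two groups). If every group has zero
#' variance the p-value is reported as missing with a reason rather than a
#' spurious number.
#'
#' @param records output of [nearest_focal_distances()] with a `condition`
#'   column.
#' @param cell_type restrict to one cell type (e.g. `"pDC"`); `NULL` uses
#'   all records.
#' @param test test name.
#' @return Object of class `condition_comparison`: per-group n and
#'   medians, the statistic and p-value, and for `"anova_tukey"` the
#'   pairwise Tukey table.
#' @export
compare_conditions <- function(records, cell_type = NULL,
                               test = c("anova_tukey", "mann_whitney",
                                        "welch_t", "wilcoxon")) {
  test <- match.arg(test)
  check_cols(records, c("condition", "d_min_um"), "distance records")
  if (!is.null(cell_type)) {
    records <- records[records$cell_type == cell_type, , drop = FALSE]
  }
  records <- records[!is.na(records$condition), , drop = FALSE]
  groups <- split(records$d_min_um, records$condition)
  if (length(groups) < 2L || any(vapply(groups, length, 1L) < 2L)) {
    stop_("need >= 2 conditions with >= 2 observations each")
  }
  res <- group_test(records$d_min_um, records$condition, test)
  summary_df <- data.frame(
    condition = names(groups),
    n = vapply(groups, length, 1L),
    median = vapply(groups, median, numeric(1)),
    mean = vapply(groups, mean, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(cell_type = cell_type, test = test, groups = summary_df,
                 statistic = res$statistic, p_value = res$p_value,
                 pairwise = res$pairwise, reason = res$reason),
            class = "condition_comparison")
}

# Shared test dispatcher; `values` numeric, `groups` character/factor.
group_test <- function(values, groups, test) {
  g <- factor(groups)
  if (sd_or_zero(values) == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, pairwise = NULL,
                reason = "zero variance in every group"))
  }
  if (test == "anova_tukey") {
    fit <- aov(values ~ g)
    tab <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$g
    pairwise <- data.frame(comparison = rownames(tk),
                           diff = tk[, "diff"], lwr = tk[, "lwr"],
                           upr = tk[, "upr"], p_adj = tk[, "p adj"],
                           row.names = NULL, stringsAsFactors = FALSE)
    list(statistic = tab[["F value"]][1], p_value = tab[["Pr(>F)"]][1],
         pairwise = pairwise, reason = NULL)
  } else {
    if (nlevels(g) != 2L) stop_("test '", test, "' requires exactly 2 groups")
    a <- values[g == levels(g)[1]]
    b <- values[g == levels(g)[2]]
    ht <- if (test == "welch_t") {
      t.test(a, b, var.equal = FALSE, alternative = "two.sided")
    } else {
      wilcox.test(a, b, alternative = "two.sided")
    }
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         pairwise = NULL, reason = NULL)
  }
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("condition_comparison (%s%s)\n", x$test,
              if (!is.null(x$cell_type)) paste0(", cell type ", x$cell_type) else ""))
  print(x$groups, row.names = FALSE)
  if (!is.null(x$reason)) {
    cat("  p-value: NA (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("  statistic = %.4g, p = %.4g\n", x$statistic, x$p_value))
    if (!is.null(x$pairwise)) {
      cat("  Tukey HSD:\n")
      print(x$pairwise, row.names = FALSE)
    }
  }
  invisible(x)
}

#' Pearson correlation with t-distribution p-value
#'
#' Thin, tested wrapper around the two-sided Pearson correlation test used
#' for score-score and score-marker relationships.
#'
#' @param x,y numeric vectors of equal length.
#' @return List with `r`, `statistic` (t), `df`, and two-sided `p_value`.
#' @export
pearson_test <- function(x, y) {
  ct <- suppressWarnings(cor.test(x, y, method = "pearson",
                                  alternative = "two.sided"))
  list(r = unname(ct$estimate), statistic = unname(ct$statistic),
       df = unname(ct$parameter), p_value = ct$p.value)
}
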