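#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end pipeline so a run is fully
#' reproducible from (inputs, config). Any element can be overridden;
#' unspecified fields keep their defaults. The configuration is plain-list,
#' JSON-serializable.
#'
#' @param seed master seed; stage seeds are fixed offsets from it.
#' @param expression arguments for [expression_sim_spec()] (without seed).
#' @param cohort list with `conditions` (named list of
#'   [tissue_sim_spec()] argument lists) and `n_samples_per_condition`.
#' @param qc arguments for [qc_thresholds()].
#' @param normalization arguments for [norm_dialect()].
#' @param scoring list: `n_bins`, `n_ctrl_per_gene`, optional `gene_set`
#'   (defaults to the simulation's true program genes).
#' @param calling list: `rule` for [call_isgt()].
#' @param proximity list: `focal_type`, `pooling`.
#' @param compare list: `test`, `cell_type` for [compare_conditions()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       expression = list(),
                       cohort = list(
                         conditions = list(
                           disease = list(attraction_sigma_um = 30),
                           control = list(attraction_sigma_um = Inf)),
                         n_samples_per_condition = 3L),
                       qc = list(),
                       normalization = list(preset = "visium"),
                       scoring = list(n_bins = 24L, n_ctrl_per_gene = 100L,
                                      gene_set = NULL),
                       calling = list(rule = "sd:3"),
                       proximity = list(focal_type = "ISG-T",
                                        pooling = "pooled_cells"),
                       compare = list(test = "anova_tukey",
                                      cell_type = "pDC")) {
  structure(list(seed = seed, expression = expression, cohort = cohort,
                 qc = qc, normalization = normalization, scoring = scoring,
                 calling = calling, proximity = proximity, compare = compare),
            class = "run_config")
}

#' Read / write a run configuration as JSON
#' @param path JSON file.
#' @param config a [run_config()].
#' @return The configuration (reader) or `path` invisibly (writer).
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  # json has no Inf: accept the string "Inf" for uniform placement
  if (!is.null(raw$cohort$conditions)) {
    raw$cohort$conditions <- lapply(raw$cohort$conditions, function(cc) {
      if (!is.null(cc$attraction_sigma_um)) {
        cc$attraction_sigma_um <- as.numeric(cc$attraction_sigma_um)
      }
      cc
    })
  }
  do.call(run_config, raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  payload <- rapply(unclass(config), function(v) {
    if (is.numeric(v)) ifelse(is.finite(v), v, "Inf") else v
  }, how = "replace")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
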