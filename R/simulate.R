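#' Specification for the expression simulator
#'
#' Defaults describe a realistic droplet-style single-cell experiment:
#' gene baseline means drawn log-normal(0, 1) (most genes near one count
#' per cell, a long right tail), negative-binomial counts with
#' variance = mu + mu^2/`nb_dispersion`, per-cell library-size factors with
#' coefficient of variation `library_size_cv`, and an interferon-stimulated
#' gene (ISG) program of `n_program_genes` genes upregulated
#' `2^program_log2fc`-fold in a `program_fraction` minority of T cells.
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param cell_type_proportions named fractions summing to 1.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters for per-gene
#'   baseline mean counts.
#' @param nb_dispersion negative-binomial size parameter; variance is
#'   mu + mu^2/dispersion.
#' @param program_genes gene identifiers carrying the ISG program, or `NULL`
#'   to use the first `n_program_genes` simulated genes (baselines are
#'   i.i.d., so this is an unbiased random program).
#' @param n_program_genes program size when `program_genes` is `NULL`.
#' @param program_log2fc log2 fold change applied to program genes in
#'   program-positive cells.
#' @param program_fraction fraction of T cells that are program-positive.
#' @param t_types cell types counted as T cells.
#' @param type_programs optional named list `type -> gene ids` of
#'   type-specific marker programs (used to make types separable for
#'   classifier tests); applied at `2^type_log2fc`.
#' @param type_log2fc log2 fold change for `type_programs`.
#' @param library_size_cv coefficient of variation of per-cell library
#'   factors (log-normal, mean 1).
#' @param seed integer RNG seed; the simulator uses its own stream.
#' @return A list of simulator parameters (class `expression_sim_spec`).
#' @export
expression_sim_spec <- function(n_cells = 2000L, n_genes = 2000L,
                                cell_type_proportions = c(T = 0.6, B = 0.15,
                                                          Myeloid = 0.15, NK = 0.1),
                                baseline_meanlog = 0, baseline_sdlog = 1,
                                nb_dispersion = 2,
                                program_genes = NULL, n_program_genes = 40L,
                                program_log2fc = 1, program_fraction = 0.05,
                                t_types = "T",
                                type_programs = NULL, type_log2fc = 2,
                                library_size_cv = 0.3, seed = 1L) {
  p <- cell_type_proportions
  if (is.null(names(p)) || any(!nzchar(names(p)))) {
    stop_("cell_type_proportions must be named")
  }
  if (abs(sum(p) - 1) > 1e-9) stop_("cell_type_proportions must sum to 1")
  if (program_fraction < 0 || program_fraction > 1) {
    stop_("program_fraction must be in [0, 1]")
  }
  if (nb_dispersion <= 0) stop_("nb_dispersion must be positive")
  if (library_size_cv < 0) stop_("library_size_cv must be nonnegative")
  structure(as.list(environment())[c(
    "n_cells", "n_genes", "cell_type_proportions", "baseline_meanlog",
    "baseline_sdlog", "nb_dispersion", "program_genes", "n_program_genes",
    "program_log2fc", "program_fraction", "t_types", "type_programs",
    "type_log2fc", "library_size_cv", "seed")], class = "expression_sim_spec")
}

#' Simulate a single-cell count matrix with a known ISG program
#'
#' Draws negative-binomial counts with per-gene log-normal baselines,
#' per-cell library factors, and a multiplicative `2^log2fc` program effect
#' on program genes in a random minority of T cells. Ground-truth
#' program-positivity is recorded in the cell table
#' (`truth_is_program_positive`).
#'
#' @param spec an [expression_sim_spec()].
#' @param sample_id,condition labels written into the cell table.
#' @return List with elements `matrix` (a raw [count_matrix()]), `cells`
#'   (cell table data.frame with truth column) and `program_genes`.
#' @export
simulate_expression <- function(spec = expression_sim_spec(),
                                sample_id = "S1", condition = "synthetic") {
  stopifnot(inherits(spec, "expression_sim_spec"))
  n <- spec$n_cells
  g <- spec$n_genes
  gene_id <- sprintf("g%05d", seq_len(g))
  prog <- spec$program_genes %||% gene_id[seq_len(min(spec$n_program_genes, g))]
  if (!all(prog %in% gene_id)) stop_("program_genes must be simulated gene ids")

  # deterministic type block sizes from the proportions
  p <- spec$cell_type_proportions
  sizes <- diff(round(cumsum(c(0, p)) * n))
  cell_type <- rep(names(p), times = sizes)
  is_T <- cell_type %in% spec$t_types
  if (spec$program_fraction > 0 && !any(is_T)) {
    stop_("program_fraction > 0 but the specification yields zero T cells")
  }

  out <- with_seed(spec$seed, {
    baseline <- rlnorm(g, spec$baseline_meanlog, spec$baseline_sdlog)
    s <- sqrt(log(1 + spec$library_size_cv^2))
    libfac <- if (s > 0) rlnorm(n, -s^2 / 2, s) else rep(1, n)
    pos <- rep(FALSE, n)
    n_pos <- round(spec$program_fraction * sum(is_T))
    if (n_pos > 0) pos[sample(which(is_T), n_pos)] <- TRUE

    mu <- outer(libfac, baseline)
    if (any(pos)) {
      j <- match(prog, gene_id)
      mu[pos, j] <- mu[pos, j] * 2^spec$program_log2fc
    }
    for (ty in names(spec$type_programs %||% list())) {
      j <- match(spec$type_programs[[ty]], gene_id)
      if (anyNA(j)) stop_("type_programs for '", ty, "' has unknown gene ids")
      rows <- cell_type == ty
      mu[rows, j] <- mu[rows, j] * 2^spec$type_log2fc
    }
    counts <- matrix(rnbinom(n * g, size = spec$nb_dispersion, mu = mu),
                     nrow = n, ncol = g)
    list(counts = counts, pos = pos)
  })

  cell_id <- sprintf("%s_c%05d", sample_id, seq_len(n))
  m <- count_matrix(out$counts, cell_ids = cell_id, gene_ids = gene_id,
                    layer = "raw")
  cells <- data.frame(cell_id = cell_id, sample_id = sample_id,
                      condition = condition, cell_type = cell_type,
                      lineage = "other", is_T = is_T,
                      truth_is_program_positive = out$pos,
                      stringsAsFactors = FALSE)
  list(matrix = m, cells = cells, program_genes = prog)
}

#' Specification for the tissue simulator
#'
#' A Thomas-style clustered point pattern: parent cells (default pDC) are
#' uniform on the rectangular domain, offspring cells (default ISG-T) are
#' isotropic Gaussian displacements (sd `attraction_sigma_um`) around a
#' uniformly chosen parent, reflected at the domain boundary so per-type
#' counts are exact; all other types are uniform. `attraction_sigma_um =
#' Inf` places the offspring uniformly (a "control" tissue with no
#' attraction). Default per-type counts describe a 4 mm^2 biopsy region
#' dominated by tubular epithelium with 50 pDCs and 100 ISG-T cells.
#'
#' @param width_um,height_um domain size in micrometers.
#' @param type_counts named integer vector of cells per type.
#' @param parent_type,offspring_type the attracting pair.
#' @param attraction_sigma_um Gaussian displacement sd in micrometers, or
#'   `Inf` for uniform offspring.
#' @param lineage_map cell-type to lineage mapping recorded in the cell
#'   table (defaults cover the default types).
#' @param t_types cell types flagged `is_T`.
#' @param seed integer RNG seed.
#' @return A list of parameters (class `tissue_sim_spec`).
#' @export
tissue_sim_spec <- function(width_um = 2000, height_um = 2000,
                            type_counts = c("ISG-T" = 100, "pDC" = 50,
                                            "PT" = 800, "EC" = 300,
                                            "FIB" = 200, "MAC" = 150,
                                            "Tn" = 200, "B" = 100),
                            parent_type = "pDC", offspring_type = "ISG-T",
                            attraction_sigma_um = 30,
                            lineage_map = c("ISG-T" = "lymphocyte",
                                            "Tn" = "lymphocyte",
                                            "B" = "lymphocyte",
                                            "pDC" = "non_lymphocyte",
                                            "PT" = "non_lymphocyte",
                                            "EC" = "non_lymphocyte",
                                            "FIB" = "non_lymphocyte",
                                            "MAC" = "non_lymphocyte"),
                            t_types = c("ISG-T", "Tn"), seed = 1L) {
  if (width_um <= 0 || height_um <= 0) stop_("domain dimensions must be positive")
  if (any(type_counts < 0)) stop_("type counts must be nonnegative")
  if (is.null(names(type_counts))) stop_("type_counts must be named")
  if (attraction_sigma_um < 0) stop_("attraction_sigma_um must be >= 0")
  structure(as.list(environment())[c(
    "width_um", "height_um", "type_counts", "parent_type", "offspring_type",
    "attraction_sigma_um", "lineage_map", "t_types", "seed")],
    class = "tissue_sim_spec")
}

# Fold a coordinate back into [lo, hi] by mirror reflection (any number of
# boundary crossings).
reflect_into <- function(v, lo, hi) {
  span <- hi - lo
  w <- (v - lo) %% (2 * span)
  lo + ifelse(w <= span, w, 2 * span - w)
}

#' Simulate a spatial cell map with parent-offspring attraction
#'
#' @param spec a [tissue_sim_spec()].
#' @param sample_id,condition labels written into the output tables.
#' @return List with `map` (data.frame `cell_id`, `x_um`, `y_um`,
#'   `sample_id`) and `cells` (cell table).
#' @export
simulate_tissue <- function(spec = tissue_sim_spec(), sample_id = "S1",
                            condition = "synthetic") {
  stopifnot(inherits(spec, "tissue_sim_spec"))
  tc <- spec$type_counts
  n_par <- if (spec$parent_type %in% names(tc)) tc[[spec$parent_type]] else 0L
  n_off <- if (spec$offspring_type %in% names(tc)) tc[[spec$offspring_type]] else 0L
  if (is.finite(spec$attraction_sigma_um) && n_off > 0 && n_par < 1) {
    stop_("finite attraction_sigma_um requires at least one parent cell")
  }

  W <- spec$width_um; H <- spec$height_um
  coords <- with_seed(spec$seed, {
    # parents first, then offspring, then the remaining types in the order
    # of type_counts: fixed draw order keeps the stream reproducible
    px <- runif(n_par, 0, W); py <- runif(n_par, 0, H)
    if (n_off > 0 && is.finite(spec$attraction_sigma_um)) {
      pick <- sample.int(n_par, n_off, replace = TRUE)
      ox <- reflect_into(px[pick] + rnorm(n_off, 0, spec$attraction_sigma_um), 0, W)
      oy <- reflect_into(py[pick] + rnorm(n_off, 0, spec$attraction_sigma_um), 0, H)
    } else {
      ox <- runif(n_off, 0, W); oy <- runif(n_off, 0, H)
    }
    other_types <- setdiff(names(tc), c(spec$parent_type, spec$offspring_type))
    ox_rest <- list(); oy_rest <- list(); ty_rest <- list()
    for (ty in other_types) {
      k <- tc[[ty]]
      ox_rest[[ty]] <- runif(k, 0, W)
      oy_rest[[ty]] <- runif(k, 0, H)
      ty_rest[[ty]] <- rep(ty, k)
    }
    data.frame(
      x_um = c(px, ox, unlist(ox_rest, use.names = FALSE)),
      y_um = c(py, oy, unlist(oy_rest, use.names = FALSE)),
      cell_type = c(rep(spec$parent_type, n_par),
                    rep(spec$offspring_type, n_off),
                    unlist(ty_rest, use.names = FALSE)),
      stringsAsFactors = FALSE)
  })

  cell_id <- sprintf("%s_c%05d", sample_id, seq_len(nrow(coords)))
  map <- data.frame(cell_id = cell_id, x_um = coords$x_um, y_um = coords$y_um,
                    sample_id = sample_id, stringsAsFactors = FALSE)
  cells <- make_cell_table(
    data.frame(cell_id = cell_id, sample_id = sample_id,
               condition = condition, cell_type = coords$cell_type,
               stringsAsFactors = FALSE),
    lineage_map = spec$lineage_map, t_types = spec$t_types)
  list(map = map, cells = cells)
}

#' Simulate a multi-sample, multi-condition tissue cohort
#'
#' Each condition is described by one [tissue_sim_spec()]; every sample in
#' the cohort gets its own seed (`base_seed + global sample index`) and a
#' sample identifier encoding its condition.
#'
#' @param condition_specs named list `condition -> tissue_sim_spec`.
#' @param n_samples_per_condition samples per condition (>= 1).
#' @param base_seed integer; per-sample seeds are offsets from it.
#' @return List with pooled `map` and `cells` data.frames across samples.
#' @export
simulate_cohort <- function(condition_specs, n_samples_per_condition = 3L,
                            base_seed = 1L) {
  if (!length(condition_specs)) stop_("at least one condition is required")
  if (is.null(names(condition_specs)) || any(!nzchar(names(condition_specs)))) {
    stop_("condition_specs must be a named list")
  }
  if (n_samples_per_condition < 1) stop_("n_samples_per_condition must be >= 1")
  maps <- list(); cells <- list(); i <- 0L
  for (cond in names(condition_specs)) {
    spec <- condition_specs[[cond]]
    stopifnot(inherits(spec, "tissue_sim_spec"))
    for (j in seq_len(n_samples_per_condition)) {
      i <- i + 1L
      spec$seed <- base_seed + i
      sid <- sprintf("%s_s%02d", cond, j)
      sim <- simulate_tissue(spec, sample_id = sid, condition = cond)
      maps[[sid]] <- sim$map
      cells[[sid]] <- sim$cells
    }
  }
  list(map = do.call(rbind, c(maps, list(make.row.names = FALSE))),
       cells = do.call(rbind, c(cells, list(make.row.names = FALSE))))
}
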