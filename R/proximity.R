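#' Per-sample distance from every non-focal cell to its nearest focal cell
#'
#' For each sample containing at least one focal cell, computes the exact
#' minimum Euclidean distance (in micrometers) from each non-focal cell to
#' its nearest focal cell. Samples without focal cells are skipped (never
#' assigned infinite distances) and listed in the `skipped_samples`
#' attribute; the focal type missing from every sample is an error.
#' Distances never cross sample boundaries. Computation is exact, blocked
#' to bound memory.
#'
#' @param map spatial table: `cell_id`, `x_um`, `y_um`, `sample_id`.
#' @param cells cell table with `cell_id`, `cell_type` (and optionally
#'   `lineage`, `condition`).
#' @param focal_type the focal cell type (e.g. `"ISG-T"`).
#' @return data.frame of distance records: `cell_id`, `sample_id`,
#'   `cell_type`, `lineage`, `condition`, `d_min_um`; attribute
#'   `skipped_samples` lists samples lacking focal cells.
#' @export
nearest_focal_distances <- function(map, cells, focal_type = "ISG-T") {
  check_cols(map, c("cell_id", "x_um", "y_um", "sample_id"), "spatial map")
  check_cols(cells, c("cell_id", "cell_type"), "cell table")
  if (!all(is.finite(map$x_um)) || !all(is.finite(map$y_um))) {
    stop_("spatial coordinates must be finite")
  }
  ann <- cells[, intersect(c("cell_id", "cell_type", "lineage", "condition"),
                           names(cells)), drop = FALSE]
  df <- merge(map, ann, by = "cell_id", sort = FALSE)
  if (!nrow(df)) stop_("no cells shared between map and cell table")
  if (!any(df$cell_type == focal_type)) {
    stop_("focal type '", focal_type, "' is absent from every sample")
  }
  if (is.null(df$lineage)) df$lineage <- "other"
  if (is.null(df$condition)) df$condition <- NA_character_

  skipped <- character()
  recs <- lapply(split(df, df$sample_id), function(s) {
    foc <- s$cell_type == focal_type
    if (!any(foc)) {
      skipped <<- c(skipped, s$sample_id[1])
      return(NULL)
    }
    oth <- s[!foc, , drop = FALSE]
    if (!nrow(oth)) return(NULL)
    d <- min_dist_blocked(oth$x_um, oth$y_um, s$x_um[foc], s$y_um[foc])
    data.frame(cell_id = oth$cell_id, sample_id = oth$sample_id,
               cell_type = oth$cell_type, lineage = oth$lineage,
               condition = oth$condition, d_min_um = d,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  if (length(skipped)) {
    isgt_log(sprintf("%d sample(s) without focal cells skipped: %s",
                     length(skipped), paste(skipped, collapse = ", ")))
  }
  attr(out, "skipped_samples") <- sort(skipped)
  attr(out, "focal_type") <- focal_type
  out
}

# Exact nearest distances from query points to reference points, computed
# in row blocks so the n x m distance matrix never fully materializes.
min_dist_blocked <- function(qx, qy, rx, ry, block = 1024L) {
  n <- length(qx)
  out <- numeric(n)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(qx[idx], rx, "-")^2 + outer(qy[idx], ry, "-")^2
    out[idx] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' Median nearest-focal distance per cell type
#'
#' Two poolings: `"pooled_cells"` takes the median over all per-cell
#' distances (the convention where reported n counts cells), while
#' `"median_of_sample_medians"` first takes the median inside each sample
#' and then the median across samples.
#'
#' @param records output of [nearest_focal_distances()].
#' @param pooling aggregation mode.
#' @param by_condition additionally split by condition.
#' @return data.frame with `cell_type` (and `condition` if requested),
#'   `lineage`, `median_um`, `n_cells`, `n_samples`, `pooling`.
#' @export
median_distance_by_type <- function(records,
                                    pooling = c("pooled_cells",
                                                "median_of_sample_medians"),
                                    by_condition = FALSE) {
  pooling <- match.arg(pooling)
  if (is.null(records) || !nrow(records)) stop_("no distance records")
  keys <- if (by_condition) list(records$cell_type, records$condition)
          else list(records$cell_type)
  groups <- split(records, keys, drop = TRUE)
  out <- lapply(groups, function(gr) {
    med <- if (pooling == "pooled_cells") {
      median(gr$d_min_um)
    } else {
      median(vapply(split(gr$d_min_um, gr$sample_id), median, numeric(1)))
    }
    data.frame(cell_type = gr$cell_type[1],
               condition = if (by_condition) gr$condition[1] else NA_character_,
               lineage = gr$lineage[1], median_um = med,
               n_cells = nrow(gr),
               n_samples = length(unique(gr$sample_id)),
               pooling = pooling, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$cell_type, res$condition, method = "radix"), , drop = FALSE]
}

#' Rank neighbour cell types around the focal type
#'
#' Within each lineage class, cell types are ranked by ascending median
#' nearest-focal distance; rank 1 is the "closest neighbour" of that class.
#' Median ties are broken by cell-type name and flagged `tied`. The result
#' is a star network with the focal type at the hub.
#'
#' @param medians output of [median_distance_by_type()] (one row per type).
#' @param focal_type hub label.
#' @return Object of class `proximity_network` with a `nodes` data.frame
#'   (`cell_type`, `lineage`, `median_um`, `n_cells`, `rank`, `closest`,
#'   `tied`).
#' @export
rank_neighbors <- function(medians, focal_type = "ISG-T") {
  check_cols(medians, c("cell_type", "lineage", "median_um"), "medians")
  med <- medians[medians$cell_type != focal_type, , drop = FALSE]
  if (anyDuplicated(med$cell_type)) {
    stop_("one row per cell type expected; aggregate conditions first")
  }
  parts <- lapply(split(med, med$lineage), function(gr) {
    ord <- order(gr$median_um, gr$cell_type, method = "radix")
    gr <- gr[ord, , drop = FALSE]
    gr$rank <- seq_len(nrow(gr))
    gr$closest <- gr$rank == 1L
    gr$tied <- duplicated(gr$median_um) | duplicated(gr$median_um, fromLast = TRUE)
    gr
  })
  nodes <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  keep <- c("cell_type", "lineage", "median_um", "n_cells", "rank",
            "closest", "tied")
  nodes <- nodes[, intersect(keep, names(nodes)), drop = FALSE]
  structure(list(focal_type = focal_type, nodes = nodes),
            class = "proximity_network")
}

#' @export
print.proximity_network <- function(x, ...) {
  cat(sprintf("proximity_network: %s at the hub, %d neighbour types\n",
              x$focal_type, nrow(x$nodes)))
  for (lin in unique(x$nodes$lineage)) {
    sub <- x$nodes[x$nodes$lineage == lin, , drop = FALSE]
    top <- sub[sub$rank == 1L, , drop = FALSE]
    cat(sprintf("  %s: closest = %s (median %.2f um; %d types)\n",
                lin, top$cell_type[1], top$median_um[1], nrow(sub)))
  }
  invisible(x)
}

#' Radial plot of a proximity network
#'
#' Draws the focal type at the centre with neighbour types arranged
#' radially, edge colour running blue (close) to red (far) and edge width
#' decreasing with distance.
#'
#' @param x a `proximity_network`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.proximity_network <- function(x, ...) {
  nodes <- x$nodes
  k <- nrow(nodes)
  theta <- seq(0, 2 * pi, length.out = k + 1L)[-1L]
  px <- cos(theta); py <- sin(theta)
  rng <- range(nodes$median_um)
  rel <- if (diff(rng) > 0) (nodes$median_um - rng[1]) / diff(rng) else rep(0.5, k)
  pal <- grDevices::colorRamp(c("blue", "red"))
  cols <- grDevices::rgb(pal(rel), maxColorValue = 255)
  graphics::plot(NA, xlim = c(-1.45, 1.45), ylim = c(-1.45, 1.45),
                 axes = FALSE, xlab = "", ylab = "", asp = 1, ...)
  graphics::segments(0, 0, px, py, col = cols, lwd = 1 + 4 * (1 - rel))
  graphics::points(0, 0, pch = 21, bg = "black", cex = 2)
  graphics::text(0, -0.12, x$focal_type, font = 2)
  graphics::points(px, py, pch = 21, bg = "grey85", cex = 1.5)
  graphics::text(1.22 * px, 1.22 * py,
                 sprintf("%s\n%.0f um", nodes$cell_type, nodes$median_um),
                 cex = 0.7)
  invisible(x)
}

#' Write a proximity network as JSON
#' @param network a `proximity_network`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_proximity_network <- function(network, path) {
  stopifnot(inherits(network, "proximity_network"))
  payload <- list(focal_type = network$focal_type, nodes = network$nodes)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
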