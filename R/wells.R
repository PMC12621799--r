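#' Quality-control filter for segmented cells
#'
#' Retains only healthy, well-isolated cells for shape quantification:
#' a cell passes if its integrated staining intensity is at least
#' `min_intensity` and at most `max_pct_touching` of its boundary touches
#' neighboring cells. Cells with undetectable cytoplasm (empty masks) are
#' always rejected. The partition is exhaustive and disjoint.
#'
#' @param cells list of [cell_mask()] objects.
#' @param min_intensity minimum integrated intensity (default 0).
#' @param max_pct_touching maximum neighbor-touching fraction in `[0, 1]`
#'   (default 0.5).
#' @return List with elements `retained` and `rejected`, each a list of
#'   `cell_mask` objects.
#' @export
filter_cells <- function(cells, min_intensity = 0, max_pct_touching = 0.5) {
  stopifnot(is.finite(min_intensity) || min_intensity == -Inf,
            max_pct_touching >= 0, max_pct_touching <= 1)
  keep <- vapply(cells, function(m) {
    sum(m$pixels) > 0L &&
      m$integrated_intensity >= min_intensity &&
      m$pct_neighbors_touching <= max_pct_touching
  }, logical(1L))
  list(retained = cells[keep], rejected = cells[!keep])
}

#' Summarize a well by per-metric medians
#'
#' The median of each morphology metric over the retained cells is the
#' representative measure of the cell population in a well (even-count
#' medians are the midpoint of the central pair). The filtered-cell count
#' is carried alongside so retained + filtered reconstructs the input
#' population.
#'
#' @param features data.frame of per-cell features (rows from
#'   [compute_features()]), all from the same well.
#' @param well_id well identifier; defaults to the one in `features`.
#' @param n_filtered number of cells removed by QC before summarization.
#' @return One-row data.frame: `well_id`, `n_cells_retained`,
#'   `n_cells_filtered`, then `median_<metric>` for each of the 15 metrics.
#' @export
summarize_well <- function(features, well_id = NULL, n_filtered = 0L) {
  if (is.null(features) || nrow(features) == 0L) {
    stop("cannot summarize an empty well", call. = FALSE)
  }
  if (is.null(well_id)) {
    well_id <- unique(features$well_id)
  }
  if (length(well_id) != 1L) {
    stop("features must come from a single well", call. = FALSE)
  }
  metrics <- morpho_metric_names()
  missing <- setdiff(metrics, names(features))
  if (length(missing)) {
    stop("features table lacks metrics: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  med <- vapply(metrics, function(m) stats::median(features[[m]]), numeric(1L))
  out <- data.frame(
    well_id = as.character(well_id),
    n_cells_retained = nrow(features),
    n_cells_filtered = as.integer(n_filtered),
    stringsAsFactors = FALSE
  )
  out[paste0("median_", metrics)] <- as.list(med)
  out
}

#' Fold-change morphology profile of treated versus control wells
#'
#' For each metric the score is the ratio of the mean treated well median
#' to the mean control well median, minus 1 — so 0 means no change and 1
#' means a doubling relative to control.
#'
#' @param treated,control data.frames of well summaries
#'   (rows from [summarize_well()]).
#' @return Named numeric vector of per-metric fold-change-minus-1 scores.
#' @export
fold_change_profile <- function(treated, control) {
  stopifnot(nrow(treated) > 0L, nrow(control) > 0L)
  metrics <- morpho_metric_names()
  cols <- paste0("median_", metrics)
  missing <- setdiff(cols, intersect(names(treated), names(control)))
  if (length(missing)) {
    stop("well summaries lack columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  t_mean <- colMeans(treated[cols])
  c_mean <- colMeans(control[cols])
  if (any(c_mean == 0)) {
    bad <- metrics[c_mean == 0]
    stop("control mean is zero for metric(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(as.numeric(t_mean / c_mean - 1), metrics)
}
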