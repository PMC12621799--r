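#' Single-cell segmentation mask
#'
#' Bundles the binary foreground raster of one segmented cell with the
#' per-cell bookkeeping the QC filter needs: integrated staining intensity
#' and the fraction of the cell boundary shared with neighboring cells.
#'
#' Pixel convention: `pixels` is a logical matrix in row-major image order,
#' 0-based pixel `(i, j)` at `pixels[i + 1, j + 1]`; physical units enter
#' only through `pixel_size` (length units per pixel, e.g. micrometres).
#'
#' Construction is permissive about mask content so that cells with
#' undetectable cytoplasm (an empty raster) can be represented and counted
#' as filtered; shape operations validate with [validate_mask()] and reject
#' empty or fragmented masks.
#'
#' @param pixels logical matrix, `TRUE` on the cell.
#' @param pixel_size physical length of one pixel side (> 0).
#' @param cell_id,well_id opaque identifiers.
#' @param integrated_intensity non-negative summed staining intensity (a.u.).
#' @param pct_neighbors_touching fraction of the boundary touching other
#'   cells, in `[0, 1]`.
#' @return An object of class `cell_mask`.
#' @seealso [compute_features()], [filter_cells()]
#' @export
cell_mask <- function(pixels, pixel_size = 1, cell_id = "cell",
                      well_id = "well", integrated_intensity = 0,
                      pct_neighbors_touching = 0) {
  if (!is.matrix(pixels) || !is.logical(pixels)) {
    stop("`pixels` must be a logical matrix", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number", call. = FALSE)
  }
  if (integrated_intensity < 0) {
    stop("`integrated_intensity` must be non-negative", call. = FALSE)
  }
  if (pct_neighbors_touching < 0 || pct_neighbors_touching > 1) {
    stop("`pct_neighbors_touching` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      pixels = pixels,
      pixel_size = pixel_size,
      cell_id = as.character(cell_id),
      well_id = as.character(well_id),
      integrated_intensity = as.numeric(integrated_intensity),
      pct_neighbors_touching = as.numeric(pct_neighbors_touching)
    ),
    class = "cell_mask"
  )
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf(
    "<cell_mask> %s (well %s): %d px, pixel_size %g, intensity %g, touching %g\n",
    x$cell_id, x$well_id, sum(x$pixels), x$pixel_size,
    x$integrated_intensity, x$pct_neighbors_touching
  ))
  invisible(x)
}

#' Count 4-connected foreground components
#'
#' @param pixels logical matrix.
#' @return Integer number of 4-connected components of `TRUE` pixels.
#' @keywords internal
mask_n_components <- function(pixels) {
  idx <- which(pixels)
  n_fg <- length(idx)
  if (n_fg == 0L) return(0L)
  if (n_fg == 1L) return(1L)
  nr <- nrow(pixels)
  nc <- ncol(pixels)
  fg_id <- integer(nr * nc)
  fg_id[idx] <- seq_len(n_fg)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  # edges to right (same row, next column) and down (next row) neighbours
  right_ok <- cols < nc & pixels[pmin(idx + nr, nr * nc)]
  down_ok <- rows < nr & pixels[pmin(idx + 1L, nr * nc)]
  edges <- rbind(
    cbind(fg_id[idx[right_ok]], fg_id[idx[right_ok] + nr]),
    cbind(fg_id[idx[down_ok]], fg_id[idx[down_ok] + 1L])
  )
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_fg - igraph::vcount(g)))
  igraph::components(g)$no
}

#' Validate a mask for shape analysis
#'
#' A mask enters shape analysis only if it has at least one foreground pixel
#' and exactly one 4-connected foreground component; anything else (empty
#' rasters from cells with undetectable cytoplasm, fragmented segmentations)
#' is rejected.
#'
#' @param mask a [cell_mask()].
#' @return `mask`, invisibly, if valid; otherwise an error.
#' @export
validate_mask <- function(mask) {
  stopifnot(inherits(mask, "cell_mask"))
  n_comp <- mask_n_components(mask$pixels)
  if (n_comp == 0L) {
    stop("invalid mask '", mask$cell_id, "': no foreground pixels",
         call. = FALSE)
  }
  if (n_comp > 1L) {
    stop("invalid mask '", mask$cell_id, "': ", n_comp,
         " disconnected foreground components (expected 1)", call. = FALSE)
  }
  invisible(mask)
}
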