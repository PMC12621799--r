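#' Convex hull of a mask's pixel corner coordinates
#'
#' The hull is taken over the corners of the foreground pixels (each pixel
#' treated as a unit square), not over pixel centers, so a one-pixel-wide
#' line still has a nonzero minimal caliper width. Only boundary pixels
#' contribute corners, which keeps the hull computation cheap on large
#' masks.
#'
#' @param mask a valid [cell_mask()].
#' @return Two-column matrix of hull vertex coordinates (x, y) in physical
#'   units, in counter-clockwise order.
#' @export
mask_convex_hull <- function(mask) {
  validate_mask(mask)
  px <- mask$pixels
  idx <- which(px)
  nr <- nrow(px)
  nc <- ncol(px)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- px
  interior <- pad[cbind(rows, cols + 1L)] & pad[cbind(rows + 2L, cols + 1L)] &
    pad[cbind(rows + 1L, cols)] & pad[cbind(rows + 1L, cols + 2L)]
  rows <- rows[!interior]
  cols <- cols[!interior]
  # corners of each boundary pixel: (col-1, row-1) .. (col, row), 0-based
  x <- c(cols - 1L, cols, cols - 1L, cols)
  y <- c(rows - 1L, rows - 1L, rows, rows)
  pts <- unique(cbind(x, y))
  h <- grDevices::chull(pts[, 1L], pts[, 2L])
  hull <- pts[rev(h), , drop = FALSE] # chull returns clockwise; reverse to CCW
  hull * mask$pixel_size
}

#' Maximal and minimal Feret (caliper) diameters
#'
#' The maximal Feret diameter is the largest caliper distance over all
#' orientations; the minimal Feret diameter is the smallest caliper width.
#' Both are computed on the convex hull of the pixel corner coordinates:
#' the maximum as the hull diameter (largest vertex-pair distance) and the
#' minimum by rotating calipers, i.e. the least over hull edges of the
#' farthest vertex distance from the edge's supporting line.
#'
#' @param mask a valid [cell_mask()].
#' @return Named numeric vector `c(max_feret, min_feret)` in physical units.
#' @export
compute_feret_diameters <- function(mask) {
  hull <- mask_convex_hull(mask)
  d <- hull_feret(hull)
  c(max_feret = d[["max_feret"]], min_feret = d[["min_feret"]])
}

#' Feret diameters of a convex polygon
#'
#' @param hull two-column coordinate matrix of convex polygon vertices.
#' @return Named vector `c(max_feret, min_feret)`.
#' @keywords internal
hull_feret <- function(hull) {
  n <- nrow(hull)
  if (n == 1L) stop("degenerate hull", call. = FALSE)
  dx <- outer(hull[, 1L], hull[, 1L], "-")
  dy <- outer(hull[, 2L], hull[, 2L], "-")
  max_f <- sqrt(max(dx * dx + dy * dy))
  # minimal width: for each edge, the farthest vertex from its line
  nxt <- c(seq_len(n)[-1L], 1L)
  ex <- hull[nxt, 1L] - hull[, 1L]
  ey <- hull[nxt, 2L] - hull[, 2L]
  len <- sqrt(ex * ex + ey * ey)
  keep <- len > 0
  ex <- ex[keep] / len[keep]
  ey <- ey[keep] / len[keep]
  x0 <- hull[keep, 1L]
  y0 <- hull[keep, 2L]
  # distance of vertex k from edge j: |cross((v_k - p_j), e_j)|
  cross <- abs(
    outer(ey, hull[, 1L]) - outer(ey * x0, rep(1, n)) -
      outer(ex, hull[, 2L]) + outer(ex * y0, rep(1, n))
  )
  min_f <- min(apply(cross, 1L, max))
  c(max_feret = max_f, min_feret = min_f)
}

#' Exhaustive projection-search Feret diameters
#'
#' Reference implementation that scans caliper orientations on a fixed
#' angular grid and measures the projection width at each: the maximum
#' width over the grid approximates the maximal Feret diameter, the
#' minimum the minimal. Used as an independent cross-check of the
#' rotating-calipers result; O(angles x vertices) and deliberately naive.
#'
#' @param hull two-column convex polygon coordinate matrix.
#' @param step_deg angular grid step in degrees.
#' @return Named vector `c(max_feret, min_feret)`.
#' @export
feret_projection_search <- function(hull, step_deg = 0.25) {
  theta <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  proj <- hull %*% rbind(cos(theta), sin(theta))
  widths <- apply(proj, 2L, max) - apply(proj, 2L, min)
  c(max_feret = max(widths), min_feret = min(widths))
}
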