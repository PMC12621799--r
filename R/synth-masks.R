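#' Configuration for synthetic cell-mask generation
#'
#' Describes a family of rasterized shapes with known geometry, standing in
#' for segmented cardiomyocyte images. For ellipses and rectangles at zero
#' boundary noise the true Feret elongation is known in closed form, which
#' is what makes these masks useful as shape-metric ground truth.
#'
#' @param shape one of `"disk"`, `"ellipse"`, `"rectangle"`, `"random_blob"`.
#' @param size_px characteristic size in pixels: disk/ellipse/blob radius
#'   (semi-minor axis for ellipses), rectangle width. Must be >= 3.
#' @param aspect_ratio length-to-width ratio >= 1 (ignored for disks).
#' @param boundary_noise_amplitude relative amplitude of smooth radial
#'   boundary perturbation, >= 0 (blobs only; 0 for exact shapes).
#' @param rotation_deg rotation of the shape in degrees (counter-clockwise).
#' @param pixel_size physical pixel size passed through to the masks.
#' @param seed RNG seed; generation is a pure function of (config, n).
#' @return A `shape_config` list.
#' @export
shape_config <- function(shape = c("disk", "ellipse", "rectangle", "random_blob"),
                         size_px = 30, aspect_ratio = 1,
                         boundary_noise_amplitude = 0, rotation_deg = 0,
                         pixel_size = 1, seed = 1L) {
  shape <- match.arg(shape)
  if (size_px < 3) stop("`size_px` must be at least 3 pixels", call. = FALSE)
  if (aspect_ratio < 1) stop("`aspect_ratio` must be >= 1", call. = FALSE)
  if (boundary_noise_amplitude < 0) {
    stop("`boundary_noise_amplitude` must be >= 0", call. = FALSE)
  }
  structure(
    list(
      shape = shape, size_px = size_px, aspect_ratio = aspect_ratio,
      boundary_noise_amplitude = boundary_noise_amplitude,
      rotation_deg = rotation_deg, pixel_size = pixel_size,
      seed = as.integer(seed)
    ),
    class = "shape_config"
  )
}

# Rasterize {x : inside(x)} on a grid of the given half-extent (px).
# inside() takes rotated shape-frame coordinates of the pixel centers.
rasterize_shape <- function(half_extent, rotation_deg, inside) {
  n <- ceiling(half_extent) + 2L
  coords <- seq_len(2L * n) - 0.5 - n # pixel centers, shape-centred
  xg <- matrix(coords, 2L * n, 2L * n, byrow = TRUE)
  yg <- matrix(coords, 2L * n, 2L * n)
  th <- -rotation_deg * pi / 180
  xr <- xg * cos(th) - yg * sin(th)
  yr <- xg * sin(th) + yg * cos(th)
  inside(xr, yr)
}

#' Generate synthetic cell masks with ground-truth geometry
#'
#' Produces `n` reproducible masks from one [shape_config()] together with a
#' ground-truth table holding the closed-form area and Feret elongation
#' where the shape admits one (disk: elongation 0; ellipse with semi-axes
#' a >= b: a/b - 1; w x l rectangle: sqrt(w^2 + l^2)/w - 1; blobs: NA).
#' Integrated intensity and neighbor-touching metadata are drawn from
#' simple seeded distributions so the masks pass straight into
#' [filter_cells()].
#'
#' @param config a [shape_config()].
#' @param n number of masks (>= 1).
#' @param well_id well identifier stamped on every mask.
#' @return List with `masks` (list of [cell_mask()]) and `truth`
#'   (data.frame: cell_id, true_area, true_feret_elongation).
#' @export
gen_cell_masks <- function(config, n = 1L, well_id = "well") {
  stopifnot(inherits(config, "shape_config"), n >= 1L)
  set.seed(config$seed)
  s <- config$size_px
  a <- config$aspect_ratio
  px <- config$pixel_size
  masks <- vector("list", n)
  truth_area <- numeric(n)
  truth_elong <- numeric(n)
  for (i in seq_len(n)) {
    if (config$shape == "disk") {
      pixels <- rasterize_shape(s, 0, function(x, y) x^2 + y^2 <= s^2)
      truth_area[i] <- pi * s^2 * px^2
      truth_elong[i] <- 0
    } else if (config$shape == "ellipse") {
      pixels <- rasterize_shape(s * a, config$rotation_deg,
                                function(x, y) (x / (s * a))^2 + (y / s)^2 <= 1)
      truth_area[i] <- pi * s^2 * a * px^2
      truth_elong[i] <- a - 1
    } else if (config$shape == "rectangle") {
      w <- s
      l <- s * a
      pixels <- rasterize_shape(l / 2 + w / 2, config$rotation_deg,
                                function(x, y) abs(x) <= l / 2 & abs(y) <= w / 2)
      truth_area[i] <- w * l * px^2
      truth_elong[i] <- sqrt(w^2 + l^2) / w - 1
    } else { # random_blob: smooth radial Fourier perturbation of a disk
      amp <- config$boundary_noise_amplitude
      ak <- stats::rnorm(4L, 0, 1)
      bk <- stats::rnorm(4L, 0, 1)
      pixels <- rasterize_shape(s * (1 + 3 * amp), config$rotation_deg,
        function(x, y) {
          th <- atan2(y, x)
          r_b <- s
          for (k in 2:5) {
            r_b <- r_b + s * amp * (ak[k - 1L] * cos(k * th) +
                                      bk[k - 1L] * sin(k * th)) / 2
          }
          sqrt(x^2 + y^2) <= pmax(r_b, 1)
        })
      truth_area[i] <- NA_real_
      truth_elong[i] <- NA_real_
    }
    masks[[i]] <- cell_mask(
      pixels = pixels, pixel_size = px,
      cell_id = sprintf("%s_%s_%03d", well_id, config$shape, i),
      well_id = well_id,
      integrated_intensity = sum(pixels) * stats::runif(1L, 0.8, 1.2),
      pct_neighbors_touching = stats::runif(1L, 0, 0.3)
    )
  }
  list(
    masks = masks,
    truth = data.frame(
      cell_id = vapply(masks, `[[`, character(1L), "cell_id"),
      true_area = truth_area,
      true_feret_elongation = truth_elong,
      stringsAsFactors = FALSE
    )
  )
}

#' Generate synthetic treated/control well-summary tables
#'
#' Emulates a per-well morphology screen: control wells fluctuate around a
#' baseline median profile, treated wells around the baseline shifted by a
#' per-metric relative effect, with additive Gaussian well-to-well noise.
#' The planted effect is recoverable by [fold_change_profile()].
#'
#' @param effects named numeric vector of relative shifts, names drawn from
#'   [morpho_metric_names()] (e.g. `c(area = 0.5)` for +50\% area);
#'   unnamed metrics shift by 0.
#' @param n_wells wells per arm (>= 2).
#' @param seed RNG seed.
#' @param baseline named baseline medians; defaults to a plausible
#'   cardiomyocyte profile in micrometre units.
#' @param noise_cv well-to-well coefficient of variation of each median.
#' @return List of data.frames `control` and `treated`, in
#'   [summarize_well()] layout.
#' @export
gen_treatment_phenotypes <- function(effects, n_wells = 6L, seed = 1L,
                                     baseline = NULL, noise_cv = 0.05) {
  stopifnot(n_wells >= 2L)
  metrics <- morpho_metric_names()
  if (is.null(baseline)) {
    baseline <- stats::setNames(
      c(2000, 250, 2200, 50, 80, 35, 85, 60, 90, 32, 1.8, 0.85, 0.4, 0.9, 0.55),
      metrics
    )
  }
  shift <- stats::setNames(numeric(length(metrics)), metrics)
  if (length(effects)) {
    unknown <- setdiff(names(effects), metrics)
    if (length(unknown)) {
      stop("unknown metrics in `effects`: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    shift[names(effects)] <- effects
  }
  set.seed(seed)
  draw_arm <- function(center, arm) {
    vals <- matrix(
      stats::rnorm(n_wells * length(metrics),
                   mean = rep(center, each = n_wells),
                   sd = rep(noise_cv * baseline, each = n_wells)),
      nrow = n_wells
    )
    out <- data.frame(
      well_id = sprintf("%s_w%02d", arm, seq_len(n_wells)),
      n_cells_retained = 100L, n_cells_filtered = 0L,
      stringsAsFactors = FALSE
    )
    out[paste0("median_", metrics)] <- as.data.frame(vals)
    out
  }
  list(
    control = draw_arm(baseline, "control"),
    treated = draw_arm(baseline * (1 + shift), "treated")
  )
}
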