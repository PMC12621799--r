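test_that("mask validation rejects empty and fragmented masks", {
  empty <- cell_mask(matrix(FALSE, 5, 5))
  expect_error(validate_mask(empty), "no foreground")
  frag_px <- matrix(FALSE, 5, 5)
  frag_px[1, 1] <- TRUE
  frag_px[5, 5] <- TRUE
  expect_error(validate_mask(cell_mask(frag_px)), "disconnected")
  # diagonal contact is not 4-connectivity
  diag_px <- matrix(FALSE, 3, 3)
  diag_px[1, 1] <- TRUE
  diag_px[2, 2] <- TRUE
  expect_error(validate_mask(cell_mask(diag_px)), "disconnected")
  ok <- matrix(TRUE, 2, 3)
  expect_silent(validate_mask(cell_mask(ok)))
})

test_that("a rasterized disk has Feret ratio near 1", {
  disk <- gen_cell_masks(shape_config("disk", size_px = 100), 1L)$masks[[1L]]
  d <- compute_feret_diameters(disk)
  expect_lt(d[["max_feret"]] / d[["min_feret"]], 1.02)
  expect_gt(d[["max_feret"]] / d[["min_feret"]], 1 - 1e-12)
})

test_that("an axis-aligned rectangle has analytic Feret diameters", {
  px <- matrix(TRUE, 50, 100) # 50 rows x 100 cols
  m <- cell_mask(px, pixel_size = 0.5)
  d <- compute_feret_diameters(m)
  expect_equal(d[["max_feret"]], sqrt(50^2 + 100^2) * 0.5, tolerance = 1e-10)
  expect_equal(d[["min_feret"]], 50 * 0.5, tolerance = 1e-10)
})

test_that("rotating calipers agree with projection-search oracle on random masks", {
  for (m in random_blob_masks(20L)) {
    hull <- mask_convex_hull(m)
    cal <- compute_feret_diameters(m)
    ora <- feret_projection_search(hull, step_deg = 0.25)
    expect_lt(abs(cal[["max_feret"]] - ora[["max_feret"]]) / ora[["max_feret"]],
              0.005)
    expect_lt(abs(cal[["min_feret"]] - ora[["min_feret"]]) / ora[["min_feret"]],
              0.005)
  }
})

test_that("the feature record has the full 15-metric panel with valid ranges", {
  m <- random_blob_masks(1L, seed_base = 7L)[[1L]]
  f <- compute_features(m)
  metrics <- morpho_metric_names()
  expect_length(metrics, 15L)
  expect_length(morpho_metric_names("size"), 10L)
  expect_length(morpho_metric_names("shape"), 5L)
  expect_setequal(setdiff(names(f), c("cell_id", "well_id")), metrics)
  expect_lte(f$area, f$convex_area)
  expect_lte(f$min_feret_diameter, f$max_feret_diameter)
  expect_gte(f$feret_elongation, 0)
  expect_true(f$form_factor > 0 && f$form_factor <= 1)
  expect_true(f$solidity > 0 && f$solidity <= 1)
  expect_true(f$eccentricity >= 0 && f$eccentricity < 1)
  expect_true(f$extent > 0 && f$extent <= 1)
  expect_error(compute_features(cell_mask(matrix(FALSE, 3, 3))),
               "no foreground")
})

test_that("Feret elongation hits its closed-form values on reference shapes", {
  disk <- gen_cell_masks(shape_config("disk", size_px = 100), 1L)$masks[[1L]]
  expect_lt(abs(compute_features(disk)$feret_elongation), 0.02)
  # 1:2 rectangle: max = diagonal, min = width => elongation sqrt(5) - 1
  rect <- cell_mask(matrix(TRUE, 40, 80))
  expect_equal(compute_features(rect)$feret_elongation, sqrt(5) - 1,
               tolerance = 0.01)
})

test_that("size metrics scale with pixel size while shape metrics do not", {
  m1 <- random_blob_masks(1L, seed_base = 21L)[[1L]]
  m3 <- cell_mask(m1$pixels, pixel_size = m1$pixel_size * 3,
                  cell_id = m1$cell_id, well_id = m1$well_id)
  f1 <- compute_features(m1)
  f3 <- compute_features(m3)
  lengths <- c("perimeter", "equivalent_diameter", "major_axis_length",
               "minor_axis_length", "bounding_box_width",
               "bounding_box_height", "max_feret_diameter",
               "min_feret_diameter")
  for (m in lengths) expect_equal(f3[[m]], 3 * f1[[m]], tolerance = 1e-9)
  for (m in c("area", "convex_area")) {
    expect_equal(f3[[m]], 9 * f1[[m]], tolerance = 1e-9)
  }
  for (m in morpho_metric_names("shape")) {
    expect_equal(f3[[m]], f1[[m]], tolerance = 0.01)
  }
})

test_that("feret elongation is robust to quarter-turn rotations", {
  m <- random_blob_masks(1L, seed_base = 33L)[[1L]]
  base <- compute_features(m)$feret_elongation
  rot90 <- function(px) t(px)[ncol(px):1, , drop = FALSE]
  px <- m$pixels
  for (k in 1:3) {
    px <- rot90(px)
    e <- compute_features(cell_mask(px))$feret_elongation
    expect_lt(abs(e - base) / max(base, 1e-9), 0.01)
  }
})

test_that("elongation increases strictly with rectangle length at fixed width", {
  elong <- vapply(seq(30, 90, by = 15), function(len) {
    compute_features(cell_mask(matrix(TRUE, 20, len)))$feret_elongation
  }, numeric(1L))
  expect_true(all(diff(elong) > 0))
})

test_that("the QC filter partitions cells by intensity and neighbor contact", {
  mk <- function(int, touch, id) {
    cell_mask(matrix(TRUE, 3, 3), cell_id = id,
              integrated_intensity = int, pct_neighbors_touching = touch)
  }
  cells <- Map(mk, c(1, 2, 3, 4, 5), c(0, 0, 0.5, 0, 0.9),
               paste0("c", 1:5))
  res <- filter_cells(cells, min_intensity = 2, max_pct_touching = 0.6)
  expect_length(res$retained, 3L)
  expect_length(res$rejected, 2L)
  expect_setequal(vapply(res$retained, `[[`, character(1L), "cell_id"),
                  c("c2", "c3", "c4"))
  # partition is exhaustive and disjoint
  expect_length(c(res$retained, res$rejected), length(cells))
  # vacuous thresholds retain everything
  all_in <- filter_cells(cells, min_intensity = -Inf, max_pct_touching = 1)
  expect_length(all_in$retained, 5L)
  # empty masks (undetectable cytoplasm) are always filtered out
  cells2 <- c(cells, list(cell_mask(matrix(FALSE, 2, 2), cell_id = "c6",
                                    integrated_intensity = 99)))
  res2 <- filter_cells(cells2, min_intensity = -Inf, max_pct_touching = 1)
  expect_setequal(vapply(res2$rejected, `[[`, character(1L), "cell_id"), "c6")
  # empty input gives two empty lists
  res0 <- filter_cells(list())
  expect_length(res0$retained, 0L)
  expect_length(res0$rejected, 0L)
})

test_that("well summaries take per-metric medians with the midpoint convention", {
  ft <- synthetic_feature_table(4L)
  ft$area <- c(1, 2, 3, 4)
  s <- summarize_well(ft, n_filtered = 2L)
  expect_equal(s$median_area, 2.5)
  expect_equal(s$n_cells_retained + s$n_cells_filtered, 6L)
  ft3 <- synthetic_feature_table(3L)
  ft3$area <- c(3, 1, 2)
  expect_equal(summarize_well(ft3)$median_area, 2)
  # sort-based oracle on a larger sample
  ft100 <- synthetic_feature_table(100L, seed = 5L)
  s100 <- summarize_well(ft100)
  for (m in morpho_metric_names()) {
    x <- sort(ft100[[m]])
    expect_equal(s100[[paste0("median_", m)]], (x[50] + x[51]) / 2)
  }
  expect_error(summarize_well(ft100[0, ]), "empty")
})

test_that("fold-change profiles recover hand-computed treated/control ratios", {
  ctrl <- do.call(rbind, lapply(1:3, function(i) {
    summarize_well(synthetic_feature_table(10L, well_id = paste0("c", i),
                                           seed = i))
  }))
  expect_equal(unname(fold_change_profile(ctrl, ctrl)),
               rep(0, 15L))
  doubled <- ctrl
  cols <- paste0("median_", morpho_metric_names())
  doubled[cols] <- 2 * doubled[cols]
  expect_equal(unname(fold_change_profile(doubled, ctrl)), rep(1, 15L))
  treat <- do.call(rbind, lapply(4:6, function(i) {
    summarize_well(synthetic_feature_table(10L, well_id = paste0("t", i),
                                           seed = i))
  }))
  fc <- fold_change_profile(treat, ctrl)
  expect_equal(fc[["area"]],
               mean(treat$median_area) / mean(ctrl$median_area) - 1)
  zero_ctrl <- ctrl
  zero_ctrl$median_area <- 0
  expect_error(fold_change_profile(treat, zero_ctrl), "zero")
})
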