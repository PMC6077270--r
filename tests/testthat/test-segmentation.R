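# Proliferating-area segmentation and the compartment partition.

make_disk_section <- function(radius = 60, level = 2000, bg = 0) {
  img <- matrix(bg, 256, 256)
  img[disk_grid <- eduquant:::disk_mask(256, 256, 128, 128, radius) == 1L] <- level
  fluorescence_section("disk", img, matrix(0, 256, 256), pixel_size_um = 4)
}

test_that("a two-level disk image segments to exactly that disk", {
  s <- make_disk_section()
  truth <- eduquant:::disk_mask(256, 256, 128, 128, 60)
  m <- segment_proliferating_area(s, smooth_sigma_px = 0, threshold = 1000,
                                  closing_radius_px = 5,
                                  min_region_area_px = 100)
  expect_identical_matrix(m$grid, truth)
})

test_that("a constant EdU channel raises a degenerate-threshold error naming the section", {
  flat <- fluorescence_section("flat_one", matrix(7, 64, 64),
                               matrix(0, 64, 64), pixel_size_um = 4)
  err <- expect_error(segment_proliferating_area(flat),
                      class = "eduquant_degenerate_threshold_error")
  expect_match(conditionMessage(err), "flat_one")
})

test_that("segmentation is deterministic", {
  sc <- small_scenario(seed = 2)
  mask <- sample_region_mask(sc)
  cells <- sample_cells(mask, 900, 20, sc$pixel_size_um, seed = 5)
  s <- render_section(mask, cells, cells, sc, seed = 6)
  a <- segment_proliferating_area(s)
  b <- segment_proliferating_area(s)
  expect_identical_matrix(a$grid, b$grid)
})

test_that("raising a fixed threshold never grows the mask", {
  sc <- small_scenario(seed = 4)
  mask <- sample_region_mask(sc)
  cells <- sample_cells(mask, 900, 20, sc$pixel_size_um, seed = 7)
  s <- render_section(mask, cells, cells, sc, seed = 8)
  sm <- eduquant:::gaussian_smooth(s$channels$edu, 8)
  thresholds <- stats::quantile(sm, c(0.5, 0.65, 0.8, 0.9), names = FALSE)
  prev <- NULL
  for (thr in thresholds) {
    m <- segment_proliferating_area(s, threshold = thr)$grid
    if (!is.null(prev)) expect_true(all(m <= prev))
    prev <- m
  }
})

test_that("compartments partition the tissue pixel-exactly", {
  sc <- small_scenario(seed = 9)
  pm <- sample_region_mask(sc)
  parts <- derive_compartment_masks(pm)
  # brute-force pixel scan
  ok_union <- TRUE; ok_disjoint <- TRUE
  pg <- parts$proliferating$grid; ng <- parts$non_proliferating$grid
  for (i in seq_len(nrow(pg))) for (j in seq_len(ncol(pg))) {
    if (pg[i, j] + ng[i, j] != 1L) ok_union <- FALSE
    if (pg[i, j] == 1L && ng[i, j] == 1L) ok_disjoint <- FALSE
  }
  expect_true(ok_union)
  expect_true(ok_disjoint)
})

test_that("compartment complement handles edge cases", {
  full <- area_mask(matrix(1L, 32, 32), "proliferating")
  parts <- derive_compartment_masks(full)
  expect_equal(sum(parts$non_proliferating$grid), 0)

  none <- area_mask(matrix(0L, 32, 32), "proliferating")
  tissue <- area_mask(matrix(1L, 32, 32), "tissue")
  parts2 <- derive_compartment_masks(none, tissue)
  expect_identical_matrix(parts2$non_proliferating$grid, tissue$grid)

  # proliferating not inside tissue -> inconsistency
  t2 <- area_mask(matrix(0L, 32, 32), "tissue")
  expect_error(derive_compartment_masks(full, t2),
               class = "eduquant_inconsistency_error")
})

test_that("segmentation recovers the simulated region at high contrast", {
  # dense labeling, no stray outside cells: the clean regime
  ious <- vapply(1:5, function(seed) {
    sc <- small_scenario(seed = seed, lambda_edu_in = 2000, lambda_edu_out = 0)
    mask <- sample_region_mask(sc)
    cells <- sample_cells(mask, 2000, 0, sc$pixel_size_um, seed = seed + 50)
    s <- render_section(mask, cells, cells[0, ], sc, seed = seed + 90)
    # closing radius scaled to the smaller region scale of this fixture
    seg <- segment_proliferating_area(s, closing_radius_px = 20,
                                      min_region_area_px = 500)
    mask_iou(seg, mask)
  }, numeric(1))
  expect_true(all(ious >= 0.90))
})
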