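# Density estimation, group comparison, report assembly.

roi_at <- function(row, col, r, comp = "proliferating") {
  structure(list(roi_id = 1L, center_row = row, center_col = col,
                 radius_px = r, compartment = comp), class = "circular_roi")
}

test_that("density arithmetic matches hand calculation", {
  # circles of radius 0.2 mm at 4 um/px -> 50 px; area = pi * 0.04 mm^2
  pix <- 4
  r_px <- 0.2 * 1000 / pix
  rois <- lapply(1:3, function(i) roi_at(100 * i, 100, r_px))
  # plant exactly 10, 12, 14 points in the three circles
  pts <- do.call(rbind, lapply(1:3, function(i) {
    n <- c(10, 12, 14)[i]
    data.frame(row = rep(100 * i, n), col = 100 + seq_len(n))
  }))
  d <- estimate_density(pts, rois, pix, sample_id = "s", channel_role = "edu")
  expect_equal(d$counts, c(10L, 12L, 14L))
  expect_equal(d$circle_area_mm2, pi * 0.04)
  expect_equal(d$mean_density, 12 / (pi * 0.04), tolerance = 1e-12)
  expect_equal(round(d$mean_density, 2), 95.49)
})

test_that("zero detections yield zero density; bad ROI sets are rejected", {
  pts <- data.frame(row = numeric(0), col = numeric(0))
  rois <- lapply(1:3, function(i) roi_at(50, 50 * i, 20))
  d <- estimate_density(pts, rois, 2)
  expect_equal(d$mean_density, 0)
  mixed <- list(roi_at(50, 50, 20), roi_at(50, 100, 25))
  expect_error(estimate_density(pts, mixed, 2),
               class = "eduquant_validation_error")
  expect_error(estimate_density(pts, list(), 2),
               class = "eduquant_validation_error")
})

test_that("density estimator is unbiased for a homogeneous process", {
  # ground-truth centroids as detections, lambda = 200 cells/mm^2
  grid <- matrix(1L, 256, 256)   # at 4 um/px: 1.048 mm^2
  lam <- 200
  ds <- vapply(1:200, function(seed) {
    cells <- sample_cells(grid, lam, 0, 4, seed = seed)
    rois <- sample_circles(grid, k = 3, radius_px = 60, seed = seed + 1000)
    estimate_density(cells, rois, 4, sample_id = "x",
                     channel_role = "edu")$mean_density
  }, numeric(1))
  expect_lt(abs(mean(ds) - lam) / lam, 0.03)
})

test_that("density variance shrinks as k grows", {
  grid <- matrix(1L, 256, 256)
  dens_k <- function(k) vapply(1:150, function(seed) {
    cells <- sample_cells(grid, 150, 0, 4, seed = seed)
    rois <- sample_circles(grid, k = k, radius_px = 40, seed = seed + 500)
    estimate_density(cells, rois, 4, sample_id = "x",
                     channel_role = "edu")$mean_density
  }, numeric(1))
  expect_lt(var(dens_k(12)), var(dens_k(3)))
})

dens_fix <- function(d, id, channel = "edu", comp = "proliferating") {
  structure(list(sample_id = id, compartment = comp, channel_role = channel,
                 counts = c(1L, 2L, 3L), circle_area_mm2 = 0.1,
                 mean_density = d, k = 3L), class = "density_estimate")
}

test_that("percent change follows 100 * (1 - treated/control)", {
  cmp <- compare_groups(dens_fix(100, "c1"), dens_fix(21.6, "t1"))
  expect_equal(cmp$percent_change, 78.4)
  expect_equal(compare_groups(dens_fix(50, "c1"),
                              dens_fix(50, "t1"))$percent_change, 0)
  # treated increase -> negative, not clamped
  expect_lt(compare_groups(dens_fix(50, "c1"),
                           dens_fix(80, "t1"))$percent_change, 0)
  expect_error(compare_groups(dens_fix(0, "c1"), dens_fix(10, "t1")),
               class = "eduquant_undefined_comparison_error")
  expect_error(compare_groups(dens_fix(10, "c1"),
                              dens_fix(10, "t1", channel = "protein")),
               class = "eduquant_validation_error")
})

test_that("swapping groups maps p to 100 * (1 - 1/(1 - p/100))", {
  for (p in c(0, 50)) {
    ctrl <- list(dens_fix(100, "c1"), dens_fix(120, "c2"))
    trt <- list(dens_fix(110 * (1 - p / 100), "t1"),
                dens_fix(110 * (1 - p / 100) * 100 / 110, "t2"))
    fwd <- compare_groups(ctrl, trt)$percent_change
    rev <- compare_groups(trt, ctrl)$percent_change
    expect_equal(rev, 100 * (1 - 1 / (1 - fwd / 100)), tolerance = 1e-9)
  }
})

test_that("bootstrap interval is seeded and covers the point estimate", {
  ctrl <- lapply(1:5, function(i) dens_fix(90 + 5 * i, paste0("c", i)))
  trt <- lapply(1:5, function(i) dens_fix(20 + 3 * i, paste0("t", i)))
  a <- compare_groups(ctrl, trt, n_boot = 200, seed = 3)
  b <- compare_groups(ctrl, trt, n_boot = 200, seed = 3)
  expect_identical(a$ci95, b$ci95)
  expect_lt(a$ci95[1], a$percent_change)
  expect_gt(a$ci95[2], a$percent_change)
})

test_that("experiment summary has the expected cardinality and order", {
  call <- classify_compartment(0.9, target_name = "p-Akt", n_cells = 100L)
  dens <- list(dens_fix(100, "c1"), dens_fix(80, "c1", channel = "protein"),
               dens_fix(30, "t1"), dens_fix(10, "t1", channel = "protein"))
  cmps <- list(compare_groups(dens[[1]], dens[[3]]),
               compare_groups(dens[[2]], dens[[4]]))
  tab <- summarize_experiment(call, dens, cmps)
  expect_equal(sum(tab$record == "density"), 4)
  expect_equal(sum(tab$record == "comparison"), 2)
  expect_equal(tab$call[tab$record == "comparison" & tab$channel == "protein"],
               "proliferating")
  # empty input -> empty table with headers
  empty <- summarize_experiment(list(), list(), list())
  expect_equal(nrow(empty), 0)
  expect_true(all(c("record", "sample_id", "channel", "percent_change")
                  %in% names(empty)))
})
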