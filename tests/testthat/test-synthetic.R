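# Simulator: region geometry, Poisson cell placement, rendering,
# experiment-level ground truth.

test_that("scenario validation rejects bad parameters", {
  expect_error(simulation_scenario(pixel_size_um = 0), class = "eduquant_validation_error")
  expect_error(simulation_scenario(lambda_edu_in = -5), class = "eduquant_validation_error")
  expect_error(simulation_scenario(psf_sigma_px = 0), class = "eduquant_validation_error")
  expect_error(simulation_scenario(blob_radius_px = c(50, 10)), class = "eduquant_validation_error")
})

test_that("a single centered blob yields a disk of the expected area", {
  sc <- simulation_scenario(image_height_px = 256L, image_width_px = 256L,
                            n_blobs = 1L, blob_radius_px = c(64, 64),
                            region_smooth_px = 6)
  grid <- eduquant:::build_region_mask(sc, centers = cbind(128.5, 128.5),
                                       radii = 64)
  expect_lt(abs(sum(grid) - pi * 64^2) / (pi * 64^2), 0.01)
  # it is one connected blob
  expect_equal(max(EBImage::bwlabel(grid)), 1)
})

test_that("region masks are deterministic and respect area bounds", {
  sc <- small_scenario(seed = 17L)
  m1 <- sample_region_mask(sc)
  m2 <- sample_region_mask(sc)
  expect_identical_matrix(m1$grid, m2$grid)
  fracs <- vapply(1:60, function(s) mean(sample_region_mask(sc, seed = s)$grid),
                  numeric(1))
  expect_true(all(fracs >= 0.05 & fracs <= 0.80))
})

test_that("cell placement follows the per-compartment Poisson law", {
  # 200 x 200 px at 10 um/px = 4 mm^2 frame; mask = full frame
  grid <- matrix(1L, 200, 200)
  counts <- vapply(1:500, function(s)
    nrow(sample_cells(grid, 100, 0, 10, seed = s)), numeric(1))
  expect_lt(abs(mean(counts) - 400) / 400, 0.02)
  expect_lt(abs(var(counts) - mean(counts)) / mean(counts), 0.15)
  # zero intensity -> no cells
  expect_equal(nrow(sample_cells(grid, 0, 0, 10, seed = 1)), 0)
  expect_error(sample_cells(grid, -1, 0, 10, seed = 1),
               class = "eduquant_validation_error")
})

test_that("cells land only in their compartment, uniformly", {
  grid <- matrix(0L, 128, 128)
  grid[, 1:64] <- 1L  # left half
  pooled <- do.call(rbind, lapply(201:230, function(s)
    sample_cells(grid, 400, 0, 8, seed = s)))
  expect_true(all(pooled$col <= 64.5))
  expect_true(all(pooled$inside))
  # uniform marginal across the mask's column extent
  ks <- suppressWarnings(stats::ks.test((pooled$col - 0.5) / 64, "punif"))
  expect_gt(ks$p.value, 0.01)
  ks_row <- suppressWarnings(stats::ks.test((pooled$row - 0.5) / 128, "punif"))
  expect_gt(ks_row$p.value, 0.01)
})

test_that("rendering: empty scene is flat, single spot peaks at amplitude", {
  sc <- small_scenario(noise_sigma = 0)
  empty <- data.frame(row = numeric(0), col = numeric(0), inside = logical(0))
  mask <- area_mask(matrix(1L, 256, 256), "tissue")
  s0 <- render_section(mask, empty, empty, sc)
  expect_true(all(s0$channels$edu == sc$background_level))
  expect_true(all(s0$channels$protein == sc$background_level))

  one <- data.frame(row = 128, col = 128, inside = TRUE)
  s1 <- render_section(mask, one, empty, sc)
  peak <- max(s1$channels$edu)
  expect_equal(which(s1$channels$edu == peak),
               128L + 256L * 127L)  # linear index of (128, 128)
  expect_lt(abs(peak - (sc$background_level + sc$spot_amplitude)) /
              (sc$background_level + sc$spot_amplitude), 0.005)
})

test_that("rendering with noise is reproducible bit for bit", {
  sc <- small_scenario(noise_sigma = 80, poisson_noise = TRUE)
  mask <- sample_region_mask(sc, seed = 3)
  cells <- sample_cells(mask, 300, 10, sc$pixel_size_um, seed = 4)
  a <- render_section(mask, cells, cells, sc, seed = 9)
  b <- render_section(mask, cells, cells, sc, seed = 9)
  expect_identical(a$channels$edu, b$channels$edu)
  expect_identical(a$channels$protein, b$channels$protein)
})

test_that("render rejects out-of-bounds cells", {
  sc <- small_scenario()
  mask <- area_mask(matrix(1L, 256, 256), "tissue")
  bad <- data.frame(row = 400, col = 10, inside = TRUE)
  empty <- data.frame(row = numeric(0), col = numeric(0), inside = logical(0))
  expect_error(render_section(mask, bad, empty, sc),
               class = "eduquant_validation_error")
})

test_that("generated experiments record the true percent change", {
  ctrl <- small_scenario(lambda_edu_in = 100, lambda_prot_in = 80)
  trt <- small_scenario(lambda_edu_in = 25, lambda_prot_in = 80)
  ex <- generate_experiment(ctrl, trt, n_per_group = 1, seed = 7)
  tc <- ex$true_change
  expect_equal(tc$true_percent_change[tc$channel == "edu" &
                                        tc$compartment == "proliferating"], 75)
  expect_equal(tc$true_percent_change[tc$channel == "protein" &
                                        tc$compartment == "proliferating"], 0)

  # control intensity zero with treated positive -> undefined (NA)
  ctrl0 <- small_scenario(lambda_edu_out = 0)
  trt0 <- small_scenario(lambda_edu_out = 5)
  ex0 <- generate_experiment(ctrl0, trt0, n_per_group = 1, seed = 7)
  tc0 <- ex0$true_change
  expect_true(is.na(tc0$true_percent_change[tc0$channel == "edu" &
                                              tc0$compartment == "non_proliferating"]))
})

test_that("experiment generation is reproducible and counts match lists", {
  ctrl <- small_scenario()
  trt <- small_scenario(lambda_edu_in = 500)
  ex1 <- generate_experiment(ctrl, trt, n_per_group = 2, seed = 11)
  ex2 <- generate_experiment(ctrl, trt, n_per_group = 2, seed = 11)
  expect_identical(
    lapply(ex1$sections, function(s) s$channels),
    lapply(ex2$sections, function(s) s$channels))
  for (tr in ex1$truth) {
    expect_equal(unname(tr$counts["edu_in"]), sum(tr$edu_cells$inside))
    expect_equal(unname(tr$counts["prot_out"]), sum(!tr$prot_cells$inside))
    expect_true(all(tr$edu_cells$row >= 0.5 &
                      tr$edu_cells$row <= 256.5))
  }
  ex3 <- generate_experiment(ctrl, trt, n_per_group = 2, seed = 12)
  expect_false(identical(ex1$sections$ctrl_01$channels$edu,
                         ex3$sections$ctrl_01$channels$edu))
})

test_that("experiments round-trip through disk", {
  ctrl <- small_scenario(lambda_edu_in = 200, lambda_prot_in = 150)
  trt <- small_scenario(lambda_edu_in = 50, lambda_prot_in = 40)
  ex <- generate_experiment(ctrl, trt, n_per_group = 1, seed = 3)
  dir <- withr::local_tempdir()
  write_experiment(ex, dir)
  expect_true(file.exists(file.path(dir, "ctrl_01_edu.tif")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  sec <- read_section(file.path(dir, "ctrl_01_edu.tif"),
                      file.path(dir, "ctrl_01_protein.tif"),
                      pixel_size_um = ctrl$pixel_size_um)
  expect_identical(dim(sec$channels$edu), dim(ex$sections$ctrl_01$channels$edu))
  # quantized write: intensities agree to the rounding unit
  expect_lt(max(abs(sec$channels$edu - ex$sections$ctrl_01$channels$edu)), 0.5 + 1e-9)
  # mask run-length encoding round-trips exactly
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  dec <- eduquant:::rle_decode_mask(gt$sections$ctrl_01$region_mask_rle)
  expect_identical_matrix(dec, ex$truth$ctrl_01$region_grid)
})
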