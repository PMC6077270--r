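# Blob detection and circle counting.

test_that("an empty noiseless scene yields no detections", {
  sc <- small_scenario(noise_sigma = 0)
  empty <- data.frame(row = numeric(0), col = numeric(0), inside = logical(0))
  mask <- area_mask(matrix(1L, 256, 256), "tissue")
  s <- render_section(mask, empty, empty, sc)
  d <- detect_positive_cells(s, "edu")
  expect_equal(nrow(d$centroids), 0)
})

test_that("a single rendered cell is found within a pixel of its center", {
  s <- render_points_section(cbind(100, 140))
  d <- detect_positive_cells(s, "edu")
  expect_equal(nrow(d$centroids), 1)
  expect_lt(sqrt((d$centroids$row - 100)^2 + (d$centroids$col - 140)^2), 1)
  expect_gt(d$centroids$peak_intensity, 0)
})

test_that("missing channel errors; flat channel with noise floor yields empty set", {
  s <- render_points_section(cbind(50, 50))
  expect_error(detect_positive_cells(s, "nope"))
  # the protein channel is identical but empty of spots
  d <- detect_positive_cells(s, "protein")
  expect_equal(nrow(d$centroids), 0)
})

test_that("detection is translation-equivariant on noiseless input", {
  pos <- cbind(c(80, 120, 167), c(60, 150, 203))
  s1 <- render_points_section(pos)
  s2 <- render_points_section(pos + 11)  # integer shift
  d1 <- detect_positive_cells(s1, "edu")$centroids
  d2 <- detect_positive_cells(s2, "edu")$centroids
  expect_equal(nrow(d1), 3)
  expect_equal(nrow(d2), 3)
  expect_equal(d2$row, d1$row + 11, tolerance = 1e-6)
  expect_equal(d2$col, d1$col + 11, tolerance = 1e-6)
})

test_that("detection matches ground truth on well-separated noisy scenes", {
  # amplitude/noise = 5, spacing >= 4 psf sigma
  f1s <- vapply(1:5, function(seed) {
    sc <- small_scenario(noise_sigma = 200, lambda_edu_in = 600,
                         lambda_edu_out = 0, seed = seed)
    mask <- area_mask(matrix(1L, 256, 256), "tissue")
    cells <- sample_cells(mask, 600, 0, sc$pixel_size_um, seed = seed + 10)
    # enforce the separation regime by greedy thinning
    keep <- rep(TRUE, nrow(cells))
    min_d2 <- (4 * sc$psf_sigma_px)^2
    for (i in seq_len(nrow(cells))) {
      if (!keep[i]) next
      if (i < nrow(cells)) {
        later <- (i + 1):nrow(cells)
        d2 <- (cells$row[later] - cells$row[i])^2 +
          (cells$col[later] - cells$col[i])^2
        keep[later][d2 < min_d2] <- FALSE
      }
    }
    cells <- cells[keep, ]
    s <- render_section(mask, cells, cells[0, ], sc, seed = seed + 20)
    d <- detect_positive_cells(s, "edu")
    match_detections(d$centroids, cells, radius = 3)$f1
  }, numeric(1))
  expect_true(all(f1s >= 0.95))
})

test_that("count_in_circle matches a brute-force scan and its conventions", {
  roi <- list(center_row = 50, center_col = 60, radius_px = 20)
  withr::with_seed(99, {
    pts <- data.frame(row = runif(200, 1, 100), col = runif(200, 1, 100))
  })
  expect_equal(count_in_circle(pts, roi), brute_count_in_circle(pts, roi))
  # empty set
  expect_equal(count_in_circle(pts[0, ], roi), 0L)
  # boundary point is included (<= convention)
  on_edge <- data.frame(row = 50, col = 80)  # distance exactly 20
  expect_equal(count_in_circle(on_edge, roi), 1L)
})

test_that("count_in_circle is monotone in radius and additive over point sets", {
  withr::with_seed(7, {
    pts <- data.frame(row = runif(150, 1, 100), col = runif(150, 1, 100))
  })
  centers <- list(c(30, 30), c(70, 55))
  for (ctr in centers) {
    prev <- -1L
    for (r in c(5, 10, 20, 40, 80)) {
      roi <- list(center_row = ctr[1], center_col = ctr[2], radius_px = r)
      n <- count_in_circle(pts, roi)
      expect_gte(n, prev)
      prev <- n
    }
  }
  roi <- list(center_row = 50, center_col = 50, radius_px = 25)
  split <- pts$row > 50
  expect_equal(count_in_circle(pts[split, ], roi) +
                 count_in_circle(pts[!split, ], roi),
               count_in_circle(pts, roi))
})

test_that("detections CSV round-trips the centroid table", {
  s <- render_points_section(cbind(c(40, 90), c(40, 200)))
  d <- detect_positive_cells(s, "edu")
  path <- withr::local_tempfile(fileext = ".csv")
  write_detections(d, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 2)
  expect_equal(back$row, d$centroids$row, tolerance = 1e-12)
  expect_equal(back$channel, rep("edu", 2))
})
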