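# Independent oracles and small fixtures used across the suite.

# Brute-force membership scan: literal loop over points, no vectorized reuse
# of the implementation under test.
brute_count_in_circle <- function(pts, roi) {
  n <- 0L
  for (i in seq_len(nrow(pts))) {
    d2 <- (pts$row[i] - roi$center_row)^2 + (pts$col[i] - roi$center_col)^2
    if (d2 <= roi$radius_px^2) n <- n + 1L
  }
  n
}

# Brute-force per-point mask membership (nearest pixel).
brute_overlap_fraction <- function(pts, grid) {
  inside <- 0L
  for (i in seq_len(nrow(pts))) {
    r <- min(max(round(pts$row[i]), 1L), nrow(grid))
    c <- min(max(round(pts$col[i]), 1L), ncol(grid))
    if (grid[r, c] == 1L) inside <- inside + 1L
  }
  inside / nrow(pts)
}

# Brute-force full-containment check for a circle in a mask: every pixel
# whose center satisfies the <= r^2 rule must be a mask pixel.
brute_circle_contained <- function(grid, roi) {
  r <- roi$radius_px
  rows <- max(1L, floor(roi$center_row - r)):min(nrow(grid), ceiling(roi$center_row + r))
  cols <- max(1L, floor(roi$center_col - r)):min(ncol(grid), ceiling(roi$center_col + r))
  for (i in rows) for (j in cols) {
    if ((i - roi$center_row)^2 + (j - roi$center_col)^2 <= r^2 &&
        grid[i, j] != 1L) return(FALSE)
  }
  TRUE
}

# Greedy globally-closest-pair bipartite matching at a match radius;
# equivalent to optimal matching when points are well separated relative to
# the radius. Returns precision/recall/F1.
match_detections <- function(det, truth, radius = 3) {
  if (nrow(det) == 0L || nrow(truth) == 0L)
    return(list(tp = 0L, precision = 0, recall = 0, f1 = 0))
  D <- outer(det$row, truth$row, "-")^2 + outer(det$col, truth$col, "-")^2
  D[D > radius^2] <- NA
  tp <- 0L
  while (!all(is.na(D))) {
    ij <- arrayInd(which.min(D), dim(D))
    tp <- tp + 1L
    D[ij[1], ] <- NA
    D[, ij[2]] <- NA
  }
  p <- tp / nrow(det); r <- tp / nrow(truth)
  list(tp = tp, precision = p, recall = r,
       f1 = if (p + r == 0) 0 else 2 * p * r / (p + r))
}

# Small fast scenario for unit tests (256 px frame, coarser pixels).
small_scenario <- function(...) {
  simulation_scenario(image_height_px = 256L, image_width_px = 256L,
                      pixel_size_um = 4, n_blobs = 2L,
                      blob_radius_px = c(40, 70), region_smooth_px = 6,
                      ...)
}

# Noiseless section with cells at given (row, col) positions in the EdU
# channel; the protein channel stays empty (flat background).
render_points_section <- function(positions, scenario = NULL,
                                  sample_id = "fixture") {
  if (is.null(scenario))
    scenario <- small_scenario(noise_sigma = 0, lambda_edu_out = 0)
  cells <- data.frame(row = positions[, 1], col = positions[, 2],
                      inside = TRUE)
  mask <- area_mask(matrix(1L, scenario$image_height_px,
                           scenario$image_width_px), "tissue")
  render_section(mask, cells, cells[0, ], scenario, sample_id = sample_id)
}

expect_identical_matrix <- function(a, b) {
  expect_true(identical(dim(a), dim(b)))
  expect_true(all(a == b))
}
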