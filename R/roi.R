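# Random circular ROI sampling inside a compartment mask. Feasibility is
# established up front from the Euclidean distance transform: a circle of
# radius r centered at a pixel lies fully inside the mask (under the
# boundary-inclusive <= r^2 pixel rule) exactly when the pixel's distance to
# the nearest background pixel exceeds r. Centers are drawn uniformly from
# that feasible set, so containment is guaranteed by construction.

#' Sample random circles fully inside a mask
#'
#' Draws `k` circle centers uniformly from the set of pixels whose distance
#' to the mask boundary exceeds `radius_px`. Circles are sampled
#' independently and may overlap unless `allow_overlap = FALSE`, in which
#' case overlapping draws are rejected (up to `max_attempts`).
#'
#' @param mask An [area_mask()] or binary matrix to sample within.
#' @param k Number of circles (>= 1). Default 3, the usual protocol.
#' @param radius_px Circle radius in pixels (>= 1), or `NULL` to use the
#'   scale-free default: the radius whose disk area equals `area_fraction`
#'   of the mask area, clamped to the largest feasible radius.
#' @param seed Integer seed.
#' @param area_fraction Disk-area fraction used when `radius_px` is `NULL`.
#'   Default 0.1.
#' @param allow_overlap If `FALSE`, returned circles are pairwise disjoint.
#' @param max_attempts Rejection bound for the non-overlapping mode.
#' @return A list of `circular_roi` objects (fields `roi_id`, `center_row`,
#'   `center_col`, `radius_px`, `compartment`), with the realized radius and
#'   seed attached as attributes `radius_px` and `seed`.
#' @export
sample_circles <- function(mask, k = 3L, radius_px = NULL, seed = 1L,
                           area_fraction = 0.1, allow_overlap = TRUE,
                           max_attempts = 10000L) {
  grid <- if (inherits(mask, "area_mask")) mask$grid else mask
  role <- if (inherits(mask, "area_mask")) mask$role else "mask"
  k <- check_count(k, "k")
  if (sum(grid) == 0L)
    stop_eduquant("cannot sample circles in an empty mask",
                  "eduquant_empty_mask_error")
  dm <- mask_distmap(grid)
  max_feasible <- max(dm) - 1e-9
  if (is.null(radius_px)) {
    check_number(area_fraction, "area_fraction", 0, strict = TRUE)
    radius_px <- sqrt(area_fraction * sum(grid) / pi)
    radius_px <- max(1, min(radius_px, floor(max_feasible)))
  }
  check_number(radius_px, "radius_px", 1)
  feasible <- which(dm > radius_px)
  if (length(feasible) == 0L)
    stop_eduquant(sprintf(
      "radius %.1f px infeasible for this mask; largest feasible radius is %.1f px",
      radius_px, max(0, max_feasible)), "eduquant_infeasible_radius_error")
  h <- nrow(grid)
  rois <- with_seed(seed, {
    draw_center <- function() {
      idx <- feasible[sample.int(length(feasible), 1L)]
      c(((idx - 1L) %% h) + 1L, ((idx - 1L) %/% h) + 1L)
    }
    out <- vector("list", k)
    i <- 1L; attempts <- 0L
    while (i <= k) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop_eduquant(sprintf(
          "could not place %d non-overlapping circles in %d attempts", k,
          max_attempts), "eduquant_infeasible_radius_error")
      ctr <- draw_center()
      if (!allow_overlap && i > 1L) {
        prev <- vapply(out[seq_len(i - 1L)], function(r)
          (r$center_row - ctr[1])^2 + (r$center_col - ctr[2])^2, numeric(1))
        if (any(prev < (2 * radius_px)^2)) next
      }
      out[[i]] <- structure(list(
        roi_id = i, center_row = ctr[1], center_col = ctr[2],
        radius_px = radius_px, compartment = role), class = "circular_roi")
      i <- i + 1L
    }
    out
  })
  attr(rois, "radius_px") <- radius_px
  attr(rois, "seed") <- seed
  rois
}

#' Largest circle radius that fits inside a mask
#'
#' @param mask An [area_mask()] or binary matrix.
#' @return The largest radius (pixels) for which [sample_circles()] is
#'   feasible; 0 for an empty mask.
#' @export
max_feasible_radius <- function(mask) {
  grid <- if (inherits(mask, "area_mask")) mask$grid else mask
  if (sum(grid) == 0L) return(0)
  max(0, max(mask_distmap(grid)) - 1e-9)
}

# Euclidean distance to the nearest background pixel, with the frame border
# itself counting as background, so a circle must also fit inside the frame.
mask_distmap <- function(grid) {
  h <- nrow(grid); w <- ncol(grid)
  padded <- matrix(0L, h + 2L, w + 2L)
  padded[2:(h + 1L), 2:(w + 1L)] <- grid
  dm <- EBImage::distmap(padded)
  dm[2:(h + 1L), 2:(w + 1L), drop = FALSE]
}

#' Write sampled ROIs to CSV
#'
#' Columns: `sample_id, roi_id, row, col, radius_px, compartment`.
#'
#' @param rois List of `circular_roi` objects from [sample_circles()].
#' @param sample_id Section identifier to record.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, sample_id, path) {
  df <- rois_to_df(rois, sample_id)
  write_table_csv(df, path)
}

rois_to_df <- function(rois, sample_id) {
  do.call(rbind, lapply(rois, function(r) data.frame(
    sample_id = sample_id, roi_id = r$roi_id, row = r$center_row,
    col = r$center_col, radius_px = r$radius_px,
    compartment = r$compartment)))
}
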