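# Compartment localization: decides whether a target protein lives in the
# proliferating or the non-proliferating compartment, which in turn selects
# where ROIs are sampled. The default metric is the fraction of detected
# protein cells whose nearest pixel falls inside the proliferating mask; an
# area-overlap alternative is available for mask-level analyses.

#' Fraction of protein detections inside the proliferating mask
#'
#' Each centroid is assigned to its nearest pixel (rounded coordinates,
#' clamped to the frame); the overlap fraction is the share of centroids on
#' mask pixels.
#'
#' @param protein_detections A `cell_detection_set` (or data.frame with
#'   `row`, `col`) for the protein channel; must contain at least one cell.
#' @param proliferating_mask An [area_mask()] aligned to the section.
#' @return A fraction in `[0, 1]`.
#' @export
compute_overlap_fraction <- function(protein_detections, proliferating_mask) {
  pts <- if (inherits(protein_detections, "cell_detection_set"))
    protein_detections$centroids else protein_detections
  grid <- if (inherits(proliferating_mask, "area_mask"))
    proliferating_mask$grid else proliferating_mask
  if (nrow(pts) == 0L)
    stop_eduquant("overlap fraction is undefined without protein detections",
                  "eduquant_undefined_fraction_error")
  ri <- pmin(pmax(round(pts$row), 1L), nrow(grid))
  ci <- pmin(pmax(round(pts$col), 1L), ncol(grid))
  mean(grid[cbind(ri, ci)] == 1L)
}

#' Area-overlap alternative metric
#'
#' Fraction of the protein-positive area (a mask) lying inside the
#' proliferating mask; offered as an alternative to the cell-count metric.
#'
#' @param protein_mask,proliferating_mask [area_mask()]s or binary matrices.
#' @return A fraction in `[0, 1]`.
#' @export
compute_area_overlap_fraction <- function(protein_mask, proliferating_mask) {
  gp <- if (inherits(protein_mask, "area_mask")) protein_mask$grid else protein_mask
  gm <- if (inherits(proliferating_mask, "area_mask"))
    proliferating_mask$grid else proliferating_mask
  stopifnot(identical(dim(gp), dim(gm)))
  if (sum(gp) == 0L)
    stop_eduquant("overlap fraction is undefined for an empty protein mask",
                  "eduquant_undefined_fraction_error")
  sum(gp & gm) / sum(gp)
}

#' Classify a target into a compartment
#'
#' Three-way call with an explicit ambiguity band: `proliferating` when the
#' overlap fraction is at least `high`, `non_proliferating` when it is at
#' most `low`, otherwise `ambiguous`. The band avoids forcing a binary call
#' on genuinely mixed expression, which would silently misdirect downstream
#' ROI sampling.
#'
#' @param overlap_fraction Fraction in `[0, 1]`, e.g. from
#'   [compute_overlap_fraction()].
#' @param low,high Band thresholds, `0 <= low < high <= 1`. Defaults 0.25 /
#'   0.75.
#' @param target_name Optional label carried into the call.
#' @param n_cells Optional number of cells the fraction was computed from.
#' @return A `compartment_call`: list with `target_name`, `overlap_fraction`,
#'   `call` (factor level), `low`, `high`, `n_cells`.
#' @export
classify_compartment <- function(overlap_fraction, low = 0.25, high = 0.75,
                                 target_name = NA_character_,
                                 n_cells = NA_integer_) {
  f <- check_number(overlap_fraction, "overlap_fraction", 0)
  if (f > 1)
    stop_eduquant("overlap_fraction must lie in [0, 1]",
                  "eduquant_validation_error")
  if (!(low < high))
    stop_eduquant("`low` must be smaller than `high`",
                  "eduquant_validation_error")
  call <- if (f >= high) "proliferating"
          else if (f <= low) "non_proliferating"
          else "ambiguous"
  structure(list(target_name = target_name, overlap_fraction = f,
                 call = call, low = low, high = high, n_cells = n_cells),
            class = "compartment_call")
}

#' @export
print.compartment_call <- function(x, ...) {
  cat(sprintf("compartment_call: %s -> %s (overlap %.3f, band [%.2f, %.2f], n = %s)\n",
              x$target_name, x$call, x$overlap_fraction, x$low, x$high,
              format(x$n_cells)))
  invisible(x)
}

#' Write compartment calls to CSV
#'
#' Columns: `target_name, n_cells, overlap_fraction, call`.
#'
#' @param calls A `compartment_call` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  if (inherits(calls, "compartment_call")) calls <- list(calls)
  df <- do.call(rbind, lapply(calls, function(x) data.frame(
    target_name = x$target_name, n_cells = x$n_cells,
    overlap_fraction = x$overlap_fraction, call = x$call)))
  write_table_csv(df, path)
}
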