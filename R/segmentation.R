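# Compartment segmentation from the EdU channel.
#
# The proliferating / non-proliferating partition of the section is the
# method's quantitative standard: every downstream count is referred to one
# of the two compartments.

#' Segment the proliferating area from the EdU channel
#'
#' Pipeline: Gaussian smooth of the EdU channel (`smooth_sigma_px`) -> global
#' threshold (Otsu on the smoothed image by default, or a fixed intensity via
#' `threshold`), with hysteresis reconstruction: connected components of the
#' weak mask (threshold lowered by `hysteresis` of the threshold-to-background
#' gap) are kept when they contain at least one strong pixel, which stops
#' shot-noise dips inside a genuinely labeled region from fragmenting the
#' mask -> binary closing with a disk (`closing_radius_px`) -> hole filling
#' -> removal of connected components smaller than `min_region_area_px`.
#' Deterministic; the parameters used are recorded in the returned mask's
#' provenance.
#'
#' @param section A [fluorescence_section()] with an `edu` channel.
#' @param smooth_sigma_px Smoothing scale in pixels. Default 8.
#' @param threshold `"otsu"` or a fixed intensity value on the smoothed
#'   image's scale.
#' @param hysteresis Fraction of the threshold-to-background gap by which
#'   the weak threshold sits below the strong one; 0 disables
#'   reconstruction. Default 0.3.
#' @param closing_radius_px Disk radius for binary closing. Default 40: large
#'   relative to the cell spacing, so that sparsely labeled sections still
#'   yield one coherent region rather than islands hugging cell clusters.
#' @param min_region_area_px Connected components smaller than this many
#'   pixels are dropped. Default 2000.
#' @return An [area_mask()] with role `"proliferating"`.
#' @export
segment_proliferating_area <- function(section,
                                       smooth_sigma_px = 8,
                                       threshold = "otsu",
                                       hysteresis = 0.3,
                                       closing_radius_px = 40,
                                       min_region_area_px = 2000) {
  stopifnot(inherits(section, "fluorescence_section"))
  img <- section$channels$edu
  if (max(img) == min(img))
    stop_eduquant(sprintf(
      "EdU channel of section '%s' is uniformly constant; threshold is degenerate",
      section$sample_id), "eduquant_degenerate_threshold_error")
  sm <- gaussian_smooth(img, smooth_sigma_px)
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(sm), range = range(sm), levels = 256L)
  } else {
    check_number(threshold, "threshold")
  }
  strong <- sm > thr
  if (hysteresis > 0 && any(strong) && !all(strong)) {
    bg <- stats::median(sm[!strong])
    thr_low <- thr - hysteresis * (thr - bg)
    lab <- EBImage::bwlabel((sm > thr_low) * 1L)
    keep_ids <- unique(lab[strong & lab > 0L])
    bin <- matrix(as.integer(lab %in% keep_ids), nrow(img), ncol(img))
  } else {
    bin <- strong * 1L
  }
  if (closing_radius_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(closing_radius_px) + 1L, "disc")
    bin <- EBImage::closing(bin, brush)
  }
  bin <- EBImage::fillHull(bin)
  lab <- EBImage::bwlabel(bin)
  if (max(lab) > 0 && min_region_area_px > 0) {
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    keep <- which(sizes >= min_region_area_px)
    bin <- matrix(as.integer(lab %in% keep), nrow(bin), ncol(bin))
  }
  storage.mode(bin) <- "integer"
  area_mask(bin, "proliferating", provenance = list(
    sample_id = section$sample_id,
    smooth_sigma_px = smooth_sigma_px,
    threshold = if (identical(threshold, "otsu")) "otsu" else threshold,
    threshold_value = thr,
    hysteresis = hysteresis,
    closing_radius_px = closing_radius_px,
    min_region_area_px = min_region_area_px))
}

#' Split a section into proliferating and non-proliferating compartments
#'
#' The non-proliferating compartment is the tissue minus the proliferating
#' mask. When no tissue mask is given the full frame counts as tissue (the
#' usual case for sections that fill the field of view). The two returned
#' masks partition the tissue exactly: disjoint, union equal to tissue.
#'
#' @param proliferating_mask An [area_mask()] with role `"proliferating"`.
#' @param tissue_mask Optional [area_mask()] with role `"tissue"`; must
#'   contain the proliferating mask.
#' @return A named list `list(proliferating =, non_proliferating =)` of
#'   [area_mask()] objects.
#' @export
derive_compartment_masks <- function(proliferating_mask, tissue_mask = NULL) {
  stopifnot(inherits(proliferating_mask, "area_mask"))
  pg <- proliferating_mask$grid
  tg <- if (is.null(tissue_mask)) {
    matrix(1L, nrow(pg), ncol(pg))
  } else {
    stopifnot(inherits(tissue_mask, "area_mask"))
    if (!identical(dim(tissue_mask$grid), dim(pg)))
      stop_eduquant("tissue and proliferating masks have different dimensions",
                    "eduquant_shape_error")
    tissue_mask$grid
  }
  if (any(pg > tg))
    stop_eduquant("proliferating mask is not a subset of the tissue mask",
                  "eduquant_inconsistency_error")
  prov <- proliferating_mask$provenance
  list(
    proliferating = area_mask(pg * tg, "proliferating", prov),
    non_proliferating = area_mask(tg * (1L - pg), "non_proliferating", prov)
  )
}

#' Low-threshold tissue detector (optional)
#'
#' Detects the tissue support as pixels above a small quantile-based
#' threshold of the smoothed total intensity, for sections that do not fill
#' the field of view. Off by default in the pipeline.
#'
#' @param section A [fluorescence_section()].
#' @param smooth_sigma_px Smoothing scale in pixels.
#' @param quantile_bg Background quantile; pixels above
#'   `quantile(smoothed, quantile_bg)` are tissue.
#' @return An [area_mask()] with role `"tissue"`.
#' @export
detect_tissue <- function(section, smooth_sigma_px = 16, quantile_bg = 0.05) {
  stopifnot(inherits(section, "fluorescence_section"))
  total <- section$channels$edu + section$channels$protein
  sm <- gaussian_smooth(total, smooth_sigma_px)
  thr <- stats::quantile(sm, quantile_bg, names = FALSE)
  grid <- EBImage::fillHull((sm >= thr) * 1L)
  storage.mode(grid) <- "integer"
  area_mask(grid, "tissue", provenance = list(
    smooth_sigma_px = smooth_sigma_px, quantile_bg = quantile_bg))
}

#' Intersection-over-union of two binary masks
#'
#' Convenience score used to validate segmentation against simulator ground
#' truth.
#'
#' @param a,b [area_mask()] objects or binary matrices of equal size.
#' @return IoU in `[0, 1]`; 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  ga <- if (inherits(a, "area_mask")) a$grid else a
  gb <- if (inherits(b, "area_mask")) b$grid else b
  stopifnot(identical(dim(ga), dim(gb)))
  inter <- sum(ga & gb); uni <- sum(ga | gb)
  if (uni == 0) 1 else inter / uni
}
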