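# Positive-cell detection: fluorescent cells appear as PSF-sized bright
# blobs; they are detected as local maxima of a multiscale scale-normalized
# Laplacian-of-Gaussian response, the standard blob statistic, after
# large-scale background subtraction. Detection runs once per section and
# channel; ROI counting then reuses the same centroids for every circle.

# Scale-normalized LoG response, computed separably:
# -sigma^2 * (Gxx (x) Gy + Gx (x) Gyy), sign chosen so bright blobs give
# positive peaks. The second-derivative kernel is re-centered to zero sum,
# so a flat image has exactly zero response everywhere.
log_kernels_1d <- function(sigma) {
  half <- max(2L, ceiling(4 * sigma))
  t <- (-half):half
  g <- exp(-t^2 / (2 * sigma^2)); g <- g / sum(g)
  g2 <- ((t^2 - sigma^2) / sigma^4) * g
  g2 <- g2 - mean(g2)
  list(g = g, g2 = g2)
}

log_response <- function(x, sigma) {
  k <- log_kernels_1d(sigma)
  B0r <- band_matrix(nrow(x), k$g);  B2r <- band_matrix(nrow(x), k$g2)
  B0c <- band_matrix(ncol(x), k$g);  B2c <- band_matrix(ncol(x), k$g2)
  -sigma^2 * (B2r %*% x %*% t(B0c) + B0r %*% x %*% t(B2c))
}

# L2 norm of the effective 2-D LoG kernel at one scale: maps an image-noise
# standard deviation to the standard deviation of the filter response.
log_kernel_norm <- function(sigma) {
  k <- log_kernels_1d(sigma)
  k2d <- sigma^2 * (outer(k$g2, k$g) + outer(k$g, k$g2))
  sqrt(sum(k2d^2))
}

neighborhood_max8 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(-Inf, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- m
  out <- matrix(-Inf, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    out <- pmax(out, p[(2L + dr):(h + 1L + dr), (2L + dc):(w + 1L + dc)])
  }
  out
}

quad_offset <- function(fm, f0, fp) {
  den <- fm - 2 * f0 + fp
  off <- ifelse(abs(den) > .Machine$double.eps, 0.5 * (fm - fp) / den, 0)
  pmin(pmax(off, -0.5), 0.5)
}

#' Detect fluorescence-positive cells in one channel
#'
#' Pipeline: estimate the smooth background by a large-scale Gaussian
#' (`background_sigma_px`) and subtract it; compute the scale-normalized
#' Laplacian-of-Gaussian blob response over `scale_factors * psf_sigma_px`;
#' keep 8-neighborhood local maxima with response at least `rel_threshold`
#' times the global maximum response; apply greedy non-maximum suppression at
#' `min_separation_px`; refine each centroid to subpixel precision by a 1-D
#' quadratic fit per axis. Deterministic. A flat channel yields an empty
#' detection set (not an error).
#'
#' @param section A [fluorescence_section()].
#' @param channel_role `"edu"` or `"protein"`.
#' @param psf_sigma_px Expected spot width in pixels (the PSF scale).
#' @param scale_factors Multipliers of `psf_sigma_px` forming the LoG scale
#'   sweep. Default `c(0.8, 1.15, 1.5)`.
#' @param background_sigma_px Background estimation scale. Default 50.
#' @param rel_threshold Response cutoff relative to the global maximum
#'   response. Default 0.10.
#' @param noise_k Absolute floor on the cutoff, in units of the robust
#'   (median/MAD) response scale; protects sparse sections, where the
#'   relative cutoff alone would drop into the noise. Default 5.
#' @param min_separation_px Minimum distance between reported centroids.
#'   Default 4.
#' @return A `cell_detection_set`: list with `section_id`, `channel_role`,
#'   `centroids` (data.frame `row`, `col`, `peak_intensity`) and
#'   `detection_params`.
#' @export
detect_positive_cells <- function(section, channel_role = c("edu", "protein"),
                                  psf_sigma_px = 2,
                                  scale_factors = c(0.8, 1.15, 1.5),
                                  background_sigma_px = 50,
                                  rel_threshold = 0.10,
                                  noise_k = 5,
                                  min_separation_px = 4) {
  stopifnot(inherits(section, "fluorescence_section"))
  channel_role <- match.arg(channel_role)
  img <- section$channels[[channel_role]]
  if (is.null(img))
    stop_eduquant(sprintf("section '%s' has no '%s' channel",
                          section$sample_id, channel_role),
                  "eduquant_validation_error")
  params <- list(psf_sigma_px = psf_sigma_px, scale_factors = scale_factors,
                 background_sigma_px = background_sigma_px,
                 rel_threshold = rel_threshold, noise_k = noise_k,
                 min_separation_px = min_separation_px)
  empty <- function() structure(list(
    section_id = section$sample_id, channel_role = channel_role,
    centroids = data.frame(row = numeric(0), col = numeric(0),
                           peak_intensity = numeric(0)),
    detection_params = params), class = "cell_detection_set")

  bg <- gaussian_smooth(img, background_sigma_px)
  resid <- img - bg
  x <- pmax(resid, 0)
  if (max(x) == 0) return(empty())

  sigmas <- psf_sigma_px * scale_factors
  resp <- matrix(-Inf, nrow(x), ncol(x))
  for (s in sigmas) resp <- pmax(resp, log_response(x, s))
  rmax <- max(resp)
  if (rmax <= 0) return(empty())

  # response cutoff: relative to the strongest blob, but never below a
  # noise floor, so a sparse section's threshold is not dragged into the
  # noise by rmax alone. The image noise scale is MAD-estimated from the
  # unrectified background residual (robust against the spots themselves)
  # and mapped to response units by the LoG kernel's L2 norm.
  sigma_noise <- stats::mad(resid, center = stats::median(resid))
  norm_max <- max(vapply(sigmas, log_kernel_norm, numeric(1)))
  cutoff <- max(rel_threshold * rmax, noise_k * sigma_noise * norm_max)
  is_peak <- resp >= neighborhood_max8(resp) & resp >= cutoff
  idx <- which(is_peak)
  if (length(idx) == 0L) return(empty())
  rr <- ((idx - 1L) %% nrow(resp)) + 1L
  cc <- ((idx - 1L) %/% nrow(resp)) + 1L
  vals <- resp[idx]

  # greedy non-maximum suppression, strongest first, via an occupancy grid:
  # a candidate is dropped if any already-kept centroid lies strictly closer
  # than min_separation_px.
  ord <- order(-vals, rr, cc)
  rr <- rr[ord]; cc <- cc[ord]
  h <- nrow(resp); w <- ncol(resp)
  m <- ceiling(min_separation_px)
  offs <- expand.grid(dr = -m:m, dc = -m:m)
  offs <- offs[offs$dr^2 + offs$dc^2 < min_separation_px^2, , drop = FALSE]
  occ <- matrix(FALSE, h, w)
  keep <- logical(length(rr))
  for (i in seq_along(rr)) {
    nr <- rr[i] + offs$dr; nc <- cc[i] + offs$dc
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    if (any(occ[cbind(nr[ok], nc[ok])])) next
    keep[i] <- TRUE
    occ[rr[i], cc[i]] <- TRUE
  }
  rr <- rr[keep]; cc <- cc[keep]

  # subpixel refinement on the pooled response map
  h <- nrow(resp); w <- ncol(resp)
  dr <- ifelse(rr > 1L & rr < h,
               quad_offset(resp[cbind(pmax(rr - 1L, 1L), cc)],
                           resp[cbind(rr, cc)],
                           resp[cbind(pmin(rr + 1L, h), cc)]), 0)
  dc <- ifelse(cc > 1L & cc < w,
               quad_offset(resp[cbind(rr, pmax(cc - 1L, 1L))],
                           resp[cbind(rr, cc)],
                           resp[cbind(rr, pmin(cc + 1L, w))]), 0)
  cent <- data.frame(row = rr + dr, col = cc + dc,
                     peak_intensity = x[cbind(rr, cc)])
  cent <- cent[order(cent$row, cent$col), , drop = FALSE]
  rownames(cent) <- NULL
  structure(list(section_id = section$sample_id, channel_role = channel_role,
                 centroids = cent, detection_params = params),
            class = "cell_detection_set")
}

#' @export
print.cell_detection_set <- function(x, ...) {
  cat(sprintf("cell_detection_set: %d cells, channel %s, section '%s'\n",
              nrow(x$centroids), x$channel_role, x$section_id))
  invisible(x)
}

#' Count detections inside a circular ROI
#'
#' Membership is boundary-inclusive: a centroid at distance exactly equal to
#' the radius is counted (`(row - c_row)^2 + (col - c_col)^2 <= r^2`).
#'
#' @param detections A `cell_detection_set` (or a data.frame with `row`,
#'   `col` columns) in the same coordinate frame as the ROI.
#' @param roi A `circular_roi` from [sample_circles()] or a list with
#'   `center_row`, `center_col`, `radius_px`.
#' @return Non-negative integer count.
#' @export
count_in_circle <- function(detections, roi) {
  pts <- if (inherits(detections, "cell_detection_set")) detections$centroids
         else detections
  if (nrow(pts) == 0L) return(0L)
  d2 <- (pts$row - roi$center_row)^2 + (pts$col - roi$center_col)^2
  sum(d2 <= roi$radius_px^2)
}

#' Write a detection set to CSV
#'
#' One row per cell: `sample_id, channel, row, col, peak_intensity`.
#'
#' @param detections A `cell_detection_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  stopifnot(inherits(detections, "cell_detection_set"))
  df <- data.frame(sample_id = detections$section_id,
                   channel = detections$channel_role,
                   detections$centroids)
  write_table_csv(df, path)
}
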