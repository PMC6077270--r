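# Ground-truthed synthetic section simulator.
#
# The generator emulates the structure the analysis method assumes: a single
# contiguous proliferating region inside the frame, EdU-positive cells
# concentrated in that region, protein-positive cells concentrated inside or
# outside it depending on the target, and treated scenarios whose cell
# intensities are reduced by a known factor. Cell placement is a homogeneous
# Poisson point process per compartment, the simplest model consistent with
# counting cells in sampled circles.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic region construction from explicit blob centers/radii:
# union of disks -> Gaussian smooth -> re-threshold at 0.5.
build_region_mask <- function(scenario, centers, radii) {
  h <- scenario$image_height_px; w <- scenario$image_width_px
  grid <- matrix(0, h, w)
  for (i in seq_along(radii)) {
    grid <- pmax(grid, disk_mask(h, w, centers[i, 1], centers[i, 2], radii[i]))
  }
  sm <- gaussian_smooth(grid, scenario$region_smooth_px)
  (sm > 0.5) * 1L
}

#' Draw the ground-truth proliferating region of a synthetic section
#'
#' Seed disks are placed uniformly in the central half of the frame, their
#' union is Gaussian-smoothed and re-thresholded at 0.5, yielding a blob-like
#' region resembling an EdU-labeled proliferating area. Geometry is redrawn
#' until the region is a single connected component occupying between 5% and
#' 80% of the frame.
#'
#' @param scenario A [simulation_scenario()].
#' @param seed Integer seed; defaults to the scenario's own seed.
#' @param max_redraws Bound on geometry redraws before failing.
#' @return An [area_mask()] with role `"proliferating"`; provenance records
#'   the accepted draw's centers, radii and attempt number.
#' @export
sample_region_mask <- function(scenario, seed = scenario$seed,
                               max_redraws = 100L) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  h <- scenario$image_height_px; w <- scenario$image_width_px
  for (attempt in seq_len(max_redraws)) {
    draw <- with_seed(mix_seed(seed, attempt), {
      centers <- cbind(runif(scenario$n_blobs, 0.25 * h, 0.75 * h),
                       runif(scenario$n_blobs, 0.25 * w, 0.75 * w))
      radii <- runif(scenario$n_blobs, scenario$blob_radius_px[1],
                     scenario$blob_radius_px[2])
      list(centers = centers, radii = radii)
    })
    grid <- build_region_mask(scenario, draw$centers, draw$radii)
    frac <- mean(grid)
    n_comp <- max(EBImage::bwlabel(grid))
    if (n_comp == 1L && frac >= 0.05 && frac <= 0.80) {
      return(area_mask(grid, "proliferating", provenance = list(
        centers = draw$centers, radii = draw$radii, attempt = attempt,
        seed = seed, smooth_px = scenario$region_smooth_px)))
    }
  }
  stop_eduquant(sprintf(
    "no admissible region geometry in %d redraws (connected, 5-80%% of frame); adjust blob number/radii",
    max_redraws), "eduquant_geometry_error")
}

#' Place cells by a per-compartment Poisson point process
#'
#' Counts inside / outside the mask are Poisson with means
#' `lambda_in * area_in_mm2` and `lambda_out * area_out_mm2`; positions are
#' uniform within each compartment (continuous coordinates, uniform over the
#' compartment's pixel support).
#'
#' @param mask An [area_mask()] or binary matrix: the inside compartment.
#' @param lambda_in,lambda_out Cell intensities, cells/mm^2, >= 0.
#' @param pixel_size_um Micrometres per pixel.
#' @param seed Integer seed.
#' @return A data.frame with columns `row`, `col` (continuous pixel
#'   coordinates) and `inside` (logical).
#' @export
sample_cells <- function(mask, lambda_in, lambda_out, pixel_size_um, seed) {
  grid <- if (inherits(mask, "area_mask")) mask$grid else mask
  check_number(lambda_in, "lambda_in", 0)
  check_number(lambda_out, "lambda_out", 0)
  check_number(pixel_size_um, "pixel_size_um", 0, strict = TRUE)
  px_mm2 <- (pixel_size_um / 1000)^2
  with_seed(seed, {
    place <- function(idx_pool, lambda, area_mm2, inside) {
      n <- if (lambda > 0 && area_mm2 > 0) rpois(1L, lambda * area_mm2) else 0L
      if (n == 0L || length(idx_pool) == 0L)
        return(data.frame(row = numeric(0), col = numeric(0),
                          inside = logical(0)))
      idx <- idx_pool[sample.int(length(idx_pool), n, replace = TRUE)]
      rr <- ((idx - 1L) %% nrow(grid)) + 1L
      cc <- ((idx - 1L) %/% nrow(grid)) + 1L
      data.frame(row = rr + runif(n, -0.5, 0.5),
                 col = cc + runif(n, -0.5, 0.5),
                 inside = rep(inside, n))
    }
    inside_idx <- which(grid == 1L)
    outside_idx <- which(grid == 0L)
    rbind(place(inside_idx, lambda_in, length(inside_idx) * px_mm2, TRUE),
          place(outside_idx, lambda_out, length(outside_idx) * px_mm2, FALSE))
  })
}

render_channel <- function(cells, scenario, noise_seed) {
  h <- scenario$image_height_px; w <- scenario$image_width_px
  img <- matrix(scenario$background_level, h, w)
  sig <- scenario$psf_sigma_px
  win <- ceiling(4 * sig)
  if (nrow(cells) > 0) {
    for (i in seq_len(nrow(cells))) {
      r0 <- cells$row[i]; c0 <- cells$col[i]
      rs <- max(1L, floor(r0 - win)):min(h, ceiling(r0 + win))
      cs <- max(1L, floor(c0 - win)):min(w, ceiling(c0 + win))
      spot <- scenario$spot_amplitude *
        exp(-(outer((rs - r0)^2, (cs - c0)^2, "+")) / (2 * sig^2))
      img[rs, cs] <- img[rs, cs] + spot
    }
  }
  with_seed(noise_seed, {
    if (scenario$poisson_noise)
      img <- matrix(rpois(length(img), pmax(img, 0)), h, w)
    if (scenario$noise_sigma > 0)
      img <- img + rnorm(length(img), 0, scenario$noise_sigma)
    pmax(img, 0)
  })
}

#' Render a two-channel section from ground-truth cells
#'
#' Each cell becomes an isotropic Gaussian spot (peak `spot_amplitude`, width
#' `psf_sigma_px`) added onto `background_level`; optional photon (Poisson)
#' noise and additive Gaussian read noise follow; intensities are clipped to
#' be non-negative. EdU cells populate the red channel, protein cells the
#' green channel.
#'
#' @param mask Ground-truth proliferating [area_mask()] (kept only for
#'   bookkeeping; rendering uses the cell lists).
#' @param edu_cells,prot_cells Cell data.frames from [sample_cells()].
#' @param scenario A [simulation_scenario()].
#' @param seed Noise seed; defaults to the scenario's seed.
#' @param sample_id,group_label,target_name Metadata for the section.
#' @return A [fluorescence_section()].
#' @export
render_section <- function(mask, edu_cells, prot_cells, scenario,
                           seed = scenario$seed,
                           sample_id = "synthetic",
                           group_label = NA_character_,
                           target_name = NA_character_) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  for (cells in list(edu_cells, prot_cells)) {
    if (nrow(cells) > 0 &&
        (min(cells$row) < 0.5 || max(cells$row) > scenario$image_height_px + 0.5 ||
         min(cells$col) < 0.5 || max(cells$col) > scenario$image_width_px + 0.5))
      stop_eduquant("cell centers outside image bounds",
                    "eduquant_validation_error")
  }
  edu <- render_channel(edu_cells, scenario, mix_seed(seed, 101L))
  prot <- render_channel(prot_cells, scenario, mix_seed(seed, 202L))
  fluorescence_section(sample_id, edu, prot, scenario$pixel_size_um,
                       group_label, target_name)
}

true_percent_change <- function(lambda_control, lambda_treated) {
  if (lambda_control == 0) {
    if (lambda_treated > 0) return(NA_real_)  # undefined: effect out of nothing
    return(0)                                 # no cells under either condition
  }
  100 * (1 - lambda_treated / lambda_control)
}

#' Simulate a control-vs-treated imaging experiment
#'
#' Draws `n_per_group` sections per arm. Each section gets its own region
#' geometry, cell draw and noise, driven by sub-seeds derived
#' deterministically from the master seed, so the whole dataset is
#' reproducible bit for bit. The generator's true percent change
#' `100 * (1 - lambda_treated / lambda_control)` is recorded per channel and
#' compartment; it is `NA` (undefined) when the control intensity is zero but
#' the treated one is not.
#'
#' @param control_scenario,treated_scenario [simulation_scenario()]s for the
#'   two arms; they should share frame geometry and optics.
#' @param n_per_group Sections per arm (>= 1).
#' @param seed Master seed.
#' @param target_name Metadata passed to the sections.
#' @return A list of class `synthetic_experiment` with elements `sections`
#'   (list of [fluorescence_section()]), `truth` (per-section ground truth:
#'   region grid, cell tables, realized counts), and `true_change` (data.frame
#'   of true percent change per channel x compartment).
#' @export
generate_experiment <- function(control_scenario, treated_scenario,
                                n_per_group, seed = 1L,
                                target_name = "target") {
  stopifnot(inherits(control_scenario, "simulation_scenario"),
            inherits(treated_scenario, "simulation_scenario"))
  n_per_group <- check_count(n_per_group, "n_per_group")
  sections <- list(); truth <- list()
  idx <- 0L
  for (group in c("control", "treated")) {
    sc <- if (group == "control") control_scenario else treated_scenario
    for (j in seq_len(n_per_group)) {
      idx <- idx + 1L
      base <- mix_seed(seed, idx)
      sample_id <- sprintf("%s_%02d", if (group == "control") "ctrl" else "trt", j)
      mask <- sample_region_mask(sc, seed = mix_seed(base, 1L))
      edu_cells <- sample_cells(mask, sc$lambda_edu_in, sc$lambda_edu_out,
                                sc$pixel_size_um, seed = mix_seed(base, 2L))
      prot_cells <- sample_cells(mask, sc$lambda_prot_in, sc$lambda_prot_out,
                                 sc$pixel_size_um, seed = mix_seed(base, 3L))
      section <- render_section(mask, edu_cells, prot_cells, sc,
                                seed = mix_seed(base, 4L),
                                sample_id = sample_id, group_label = group,
                                target_name = target_name)
      sections[[sample_id]] <- section
      truth[[sample_id]] <- structure(list(
        sample_id = sample_id, group_label = group,
        region_grid = mask$grid,
        edu_cells = edu_cells, prot_cells = prot_cells,
        counts = c(edu_in = sum(edu_cells$inside),
                   edu_out = sum(!edu_cells$inside),
                   prot_in = sum(prot_cells$inside),
                   prot_out = sum(!prot_cells$inside)),
        scenario = sc), class = "ground_truth")
    }
  }
  cs <- control_scenario; ts <- treated_scenario
  true_change <- data.frame(
    channel = c("edu", "edu", "protein", "protein"),
    compartment = c("proliferating", "non_proliferating",
                    "proliferating", "non_proliferating"),
    true_percent_change = c(
      true_percent_change(cs$lambda_edu_in, ts$lambda_edu_in),
      true_percent_change(cs$lambda_edu_out, ts$lambda_edu_out),
      true_percent_change(cs$lambda_prot_in, ts$lambda_prot_in),
      true_percent_change(cs$lambda_prot_out, ts$lambda_prot_out)))
  structure(list(sections = sections, truth = truth,
                 true_change = true_change, seed = seed,
                 control_scenario = control_scenario,
                 treated_scenario = treated_scenario),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  n <- length(x$sections)
  cat(sprintf("synthetic_experiment: %d sections (%d per group), master seed %d\n",
              n, n %/% 2L, x$seed))
  print(x$true_change)
  invisible(x)
}

# Run-length encoding of a binary mask (column-major), for JSON ground truth.
rle_encode_mask <- function(grid) {
  r <- rle(as.integer(grid))
  list(nrow = nrow(grid), ncol = ncol(grid),
       values = r$values, lengths = r$lengths)
}

rle_decode_mask <- function(enc) {
  v <- inverse.rle(list(values = as.integer(enc$values),
                        lengths = as.integer(enc$lengths)))
  matrix(v, enc$nrow, enc$ncol)
}

#' Write a simulated experiment to disk
#'
#' Images go out as per-channel 16-bit grayscale TIFFs named
#' `{sample_id}_{channel}.tif` (intensities clipped to the fixed 0..65535
#' dynamic range and rounded), scenarios as YAML, and ground truth as JSON
#' (masks run-length encoded, cell tables inline).
#'
#' @param experiment A `synthetic_experiment`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (section in experiment$sections) write_section(section, dir)
  write_scenario(experiment$control_scenario,
                 file.path(dir, "scenario_control.yaml"))
  write_scenario(experiment$treated_scenario,
                 file.path(dir, "scenario_treated.yaml"))
  truth <- lapply(experiment$truth, function(tr) {
    list(sample_id = tr$sample_id, group_label = tr$group_label,
         region_mask_rle = rle_encode_mask(tr$region_grid),
         edu_cells = tr$edu_cells, prot_cells = tr$prot_cells,
         counts = as.list(tr$counts))
  })
  jsonlite::write_json(
    list(seed = experiment$seed, true_change = experiment$true_change,
         sections = truth),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
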