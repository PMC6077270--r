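#' Define a synthetic tumor-section scenario
#'
#' A `simulation_scenario` bundles everything needed to draw one ground-truthed
#' two-channel section: frame size and pixel calibration, the geometry of the
#' proliferating region, per-compartment cell intensities for the EdU and
#' protein channels, and the optical rendering/noise model. The same scenario
#' plus the same seed reproduces the same section bit for bit.
#'
#' Cell placement is a homogeneous Poisson point process per compartment:
#' the number of cells in a compartment is Poisson with mean
#' \eqn{\lambda \times area_{mm^2}} and positions are uniform within it.
#' Intensities \eqn{\lambda} are expressed in cells per square millimetre.
#'
#' @param image_height_px,image_width_px Frame size in pixels.
#' @param pixel_size_um Pixel calibration, micrometres per pixel (> 0).
#' @param n_blobs Number of seed disks whose smoothed union forms the
#'   proliferating region.
#' @param blob_radius_px Length-2 range (min, max) of seed-disk radii, pixels.
#' @param region_smooth_px Gaussian smoothing scale applied to the blob union
#'   before re-thresholding at 0.5, pixels.
#' @param lambda_edu_in,lambda_edu_out EdU-positive cell intensity
#'   (cells/mm^2) inside / outside the proliferating region.
#' @param lambda_prot_in,lambda_prot_out Protein-positive cell intensity
#'   (cells/mm^2) inside / outside the proliferating region. A
#'   proliferating-compartment target (Akt-like) has `lambda_prot_in >>
#'   lambda_prot_out`; a non-proliferating target (HIF-1a-like) the reverse.
#' @param psf_sigma_px Gaussian width of a rendered cell spot, pixels.
#' @param spot_amplitude Peak intensity a single rendered cell adds above
#'   background (arbitrary intensity units, 16-bit writable range).
#' @param background_level Constant background intensity.
#' @param noise_sigma Standard deviation of additive Gaussian read noise
#'   (0 disables).
#' @param poisson_noise If `TRUE`, photon (Poisson) noise is applied to the
#'   noiseless intensity before the additive term.
#' @param seed Integer seed owned by the scenario; used when no explicit seed
#'   is passed to the sampling functions.
#'
#' @return An object of class `simulation_scenario` (a validated list).
#' @examples
#' sc <- simulation_scenario(image_height_px = 256, image_width_px = 256,
#'                           pixel_size_um = 4)
#' sc$lambda_edu_in
#' @export
simulation_scenario <- function(image_height_px = 512L,
                                image_width_px = 512L,
                                pixel_size_um = 2,
                                n_blobs = 3L,
                                blob_radius_px = c(80, 140),
                                region_smooth_px = 10,
                                lambda_edu_in = 1000,
                                lambda_edu_out = 20,
                                lambda_prot_in = 800,
                                lambda_prot_out = 20,
                                psf_sigma_px = 2,
                                spot_amplitude = 1000,
                                background_level = 100,
                                noise_sigma = 100,
                                poisson_noise = FALSE,
                                seed = 1L) {
  sc <- list(
    image_height_px = check_count(image_height_px, "image_height_px"),
    image_width_px = check_count(image_width_px, "image_width_px"),
    pixel_size_um = check_number(pixel_size_um, "pixel_size_um", 0, strict = TRUE),
    n_blobs = check_count(n_blobs, "n_blobs"),
    blob_radius_px = blob_radius_px,
    region_smooth_px = check_number(region_smooth_px, "region_smooth_px", 0),
    lambda_edu_in = check_number(lambda_edu_in, "lambda_edu_in", 0),
    lambda_edu_out = check_number(lambda_edu_out, "lambda_edu_out", 0),
    lambda_prot_in = check_number(lambda_prot_in, "lambda_prot_in", 0),
    lambda_prot_out = check_number(lambda_prot_out, "lambda_prot_out", 0),
    psf_sigma_px = check_number(psf_sigma_px, "psf_sigma_px", 0, strict = TRUE),
    spot_amplitude = check_number(spot_amplitude, "spot_amplitude", 0),
    background_level = check_number(background_level, "background_level", 0),
    noise_sigma = check_number(noise_sigma, "noise_sigma", 0),
    poisson_noise = isTRUE(poisson_noise),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (length(sc$blob_radius_px) == 1L)
    sc$blob_radius_px <- rep(sc$blob_radius_px, 2L)
  if (length(sc$blob_radius_px) != 2L || any(sc$blob_radius_px <= 0) ||
      sc$blob_radius_px[1] > sc$blob_radius_px[2])
    stop_eduquant("`blob_radius_px` must be a positive (min, max) pair",
                  "eduquant_validation_error")
  structure(sc, class = "simulation_scenario")
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat(sprintf("simulation_scenario: %d x %d px @ %g um/px (%.3f mm^2)\n",
              x$image_height_px, x$image_width_px, x$pixel_size_um,
              x$image_height_px * x$image_width_px * (x$pixel_size_um / 1000)^2))
  cat(sprintf("  region: %d blobs, radius %g-%g px, smooth %g px\n",
              x$n_blobs, x$blob_radius_px[1], x$blob_radius_px[2],
              x$region_smooth_px))
  cat(sprintf("  lambda edu in/out: %g / %g, protein in/out: %g / %g cells/mm^2\n",
              x$lambda_edu_in, x$lambda_edu_out,
              x$lambda_prot_in, x$lambda_prot_out))
  cat(sprintf("  psf sigma %g px, amplitude %g, background %g, noise sigma %g%s, seed %d\n",
              x$psf_sigma_px, x$spot_amplitude, x$background_level,
              x$noise_sigma, if (x$poisson_noise) " + Poisson" else "", x$seed))
  invisible(x)
}

#' Read or write a scenario as YAML
#'
#' Scenario files store the `simulation_scenario` fields verbatim, so a
#' simulated experiment can be reproduced from its recorded scenario alone.
#'
#' @param path File path.
#' @param scenario A `simulation_scenario`.
#' @return `read_scenario` returns a `simulation_scenario`;
#'   `write_scenario` returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(simulation_scenario, vals)
}

#' @rdname read_scenario
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  yaml::write_yaml(unclass(scenario), path)
  invisible(path)
}
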