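# File I/O: TIFF/PNG channel images in, TIFF masks + CSV tables + JSON
# provenance out, YAML configuration.
#
# Images are held internally as non-negative real matrices indexed
# [row, col], 1-based, pixel centers at integer coordinates. On disk the
# dynamic range is fixed: 16-bit grayscale, intensities clipped to
# [0, 65535] and rounded.

read_channel_file <- function(path, channel_index = NULL) {
  if (!file.exists(path))
    stop_eduquant(sprintf("image file not found: '%s'", path),
                  "eduquant_format_error")
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    tryCatch(tiff::readTIFF(path, as.is = TRUE),
             error = function(e) stop_eduquant(
               sprintf("cannot read TIFF '%s': %s", path, conditionMessage(e)),
               "eduquant_format_error"))
  } else if (ext == "png") {
    # readPNG scales to [0, 1]; restore the package's 16-bit dynamic range
    tryCatch(png::readPNG(path) * 65535,
             error = function(e) stop_eduquant(
               sprintf("cannot read PNG '%s': %s", path, conditionMessage(e)),
               "eduquant_format_error"))
  } else {
    stop_eduquant(sprintf("unsupported image format '%s' for '%s'", ext, path),
                  "eduquant_format_error")
  }
  if (length(dim(img)) == 3L) {
    if (is.null(channel_index)) {
      if (dim(img)[3] == 1L) channel_index <- 1L
      else stop_eduquant(sprintf(
        "'%s' is multichannel (%d channels); a channel index is required",
        path, dim(img)[3]), "eduquant_format_error")
    }
    if (channel_index > dim(img)[3])
      stop_eduquant(sprintf("channel index %d out of range for '%s'",
                            channel_index, path), "eduquant_format_error")
    img <- img[, , channel_index]
  }
  if (!is.matrix(img))
    stop_eduquant(sprintf("'%s' did not decode to a 2-D grayscale image", path),
                  "eduquant_format_error")
  storage.mode(img) <- "double"
  pmax(img, 0)
}

#' Read a two-channel section from image files
#'
#' Accepts either one single-channel 8/16-bit grayscale TIFF or PNG per
#' channel, or one multichannel TIFF with a channel-index map.
#'
#' @param edu,protein File paths. When `protein` is `NULL`, `edu` must be a
#'   multichannel file and `channel_map` selects the planes.
#' @param pixel_size_um Micrometres per pixel.
#' @param sample_id Sample identifier; defaults to the EdU file's base name.
#' @param group_label,target_name Metadata (see [fluorescence_section()]).
#' @param channel_map Named list/indices `list(edu =, protein =)` into a
#'   multichannel file.
#' @return A [fluorescence_section()].
#' @export
read_section <- function(edu, protein = NULL, pixel_size_um,
                         sample_id = NULL, group_label = NA_character_,
                         target_name = NA_character_, channel_map = NULL) {
  if (is.null(sample_id))
    sample_id <- sub("_(edu|protein)$", "",
                     tools::file_path_sans_ext(basename(edu)))
  if (is.null(protein)) {
    if (is.null(channel_map) || is.null(channel_map$edu) ||
        is.null(channel_map$protein))
      stop_eduquant("multichannel input needs channel_map$edu and channel_map$protein",
                    "eduquant_format_error")
    e <- read_channel_file(edu, channel_map$edu)
    p <- read_channel_file(edu, channel_map$protein)
  } else {
    e <- read_channel_file(edu)
    p <- read_channel_file(protein)
  }
  fluorescence_section(sample_id, e, p, pixel_size_um, group_label, target_name)
}

#' Write a section as per-channel 16-bit TIFFs
#'
#' Files are named `{sample_id}_{channel}.tif`; intensities are clipped to
#' the fixed `[0, 65535]` range and rounded.
#'
#' @param section A [fluorescence_section()].
#' @param dir Output directory.
#' @return Character vector of the two written paths, invisibly.
#' @export
write_section <- function(section, dir) {
  stopifnot(inherits(section, "fluorescence_section"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (role in c("edu", "protein")) {
    img <- round(pmin(pmax(section$channels[[role]], 0), 65535))
    path <- file.path(dir, sprintf("%s_%s.tif", section$sample_id, role))
    tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L,
                    compression = "none")
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Write / read a binary mask as 8-bit TIFF
#'
#' Masks are stored as 0/255 single-channel TIFFs; the mask's provenance is
#' written to a JSON sidecar (`<path>.json`).
#'
#' @param mask An [area_mask()].
#' @param path Output TIFF path.
#' @param role Compartment role to assign on reading.
#' @return `write_mask` returns `path` invisibly; `read_mask` returns an
#'   [area_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "area_mask"))
  tiff::writeTIFF(mask$grid * 1.0, path, bits.per.sample = 8L,
                  compression = "none")
  jsonlite::write_json(c(list(role = mask$role), mask$provenance),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, role = "proliferating") {
  grid <- (tiff::readTIFF(path, as.is = TRUE) > 0) * 1L
  prov <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) prov <- jsonlite::read_json(sidecar)
  area_mask(grid, role = prov$role %||% role, provenance = prov)
}

#' Default pipeline configuration
#'
#' All stage parameters with their defaults, as one named list mirroring the
#' YAML layout. `read_config()` merges a user file over these values.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    pixel_size_um = NULL,
    seed = 1L,
    target_name = "target",
    image_dir = ".",
    samples = list(),
    compartment = NULL,  # force "proliferating"/"non_proliferating"; NULL = auto
    segmentation = list(smooth_sigma_px = 8, threshold = "otsu", hysteresis = 0.3,
                        closing_radius_px = 40, min_region_area_px = 2000,
                        tissue_detector = FALSE),
    detection = list(psf_sigma_px = 2, scale_factors = c(0.8, 1.15, 1.5),
                     background_sigma_px = 50, rel_threshold = 0.10,
                     noise_k = 5, min_separation_px = 4),
    localization = list(low = 0.25, high = 0.75),
    sampling = list(k = 3L, radius_px = NULL, area_fraction = 0.1,
                    allow_overlap = TRUE),
    quantification = list(n_boot = 0L)
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) && nm != "samples")
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Read and validate a pipeline configuration
#'
#' A single YAML file carries the channel-role file mapping, pixel
#' calibration, group assignment per sample, every stage parameter block and
#' the master seed. Validation happens before any computation: pixel size
#' present and positive, every referenced image file exists, both channel
#' roles covered, groups valid.
#'
#' @param path YAML config path.
#' @param check_files If `TRUE` (default) referenced image files must exist.
#' @return Validated config list (class `eduquant_config`); sample file
#'   paths are resolved relative to `image_dir`, itself resolved relative to
#'   the config file.
#' @export
read_config <- function(path, check_files = TRUE) {
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_config(), user)
  if (is.null(cfg$pixel_size_um))
    stop_eduquant("config is missing pixel_size_um", "eduquant_validation_error")
  check_number(cfg$pixel_size_um, "pixel_size_um", 0, strict = TRUE)
  check_count(cfg$seed, "seed", min = 0L)
  if (length(cfg$samples) == 0L)
    stop_eduquant("config lists no samples", "eduquant_validation_error")
  base_dir <- dirname(normalizePath(path))
  img_dir <- cfg$image_dir
  if (!grepl("^(/|[A-Za-z]:)", img_dir))
    img_dir <- file.path(base_dir, img_dir)
  for (i in seq_along(cfg$samples)) {
    s <- cfg$samples[[i]]
    for (fld in c("sample_id", "group"))
      if (is.null(s[[fld]]))
        stop_eduquant(sprintf("sample %d is missing '%s'", i, fld),
                      "eduquant_validation_error")
    if (!s$group %in% c("control", "treated"))
      stop_eduquant(sprintf("sample '%s': group must be control or treated",
                            s$sample_id), "eduquant_validation_error")
    if (is.null(s$edu) || (is.null(s$protein) && is.null(s$channel_map)))
      stop_eduquant(sprintf(
        "sample '%s' must map both channel roles (edu + protein files, or a multichannel file with channel_map)",
        s$sample_id), "eduquant_validation_error")
    for (fld in c("edu", "protein")) {
      if (is.null(s[[fld]])) next
      p <- s[[fld]]
      if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(img_dir, p)
      if (check_files && !file.exists(p))
        stop_eduquant(sprintf("sample '%s': file not found: '%s'",
                              s$sample_id, p), "eduquant_format_error")
      cfg$samples[[i]][[fld]] <- p
    }
  }
  structure(cfg, class = c("eduquant_config", "list"))
}

config_hash <- function(cfg) {
  string_hash31(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                                 null = "null"))
}

provenance_record <- function(cfg, extra = list()) {
  c(list(package = "eduquant",
         version = as.character(utils::packageVersion("eduquant")),
         config_hash = config_hash(cfg),
         seed = cfg$seed,
         config = unclass(cfg)),
    extra)
}
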