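#' Two-channel fluorescence section
#'
#' The pipeline's raw input: a red EdU channel marking proliferating cells and
#' a green immunofluorescence channel for a target protein, both as
#' non-negative intensity matrices of equal size, plus pixel calibration and
#' group/target metadata.
#'
#' Coordinate convention (shared by masks, detections and ROIs throughout the
#' package): matrices are indexed `[row, col]`, 1-based, with pixel centers at
#' integer coordinates.
#'
#' @param sample_id Sample identifier string.
#' @param edu,protein Numeric matrices of identical dimensions, intensities
#'   >= 0.
#' @param pixel_size_um Micrometres per pixel (> 0).
#' @param group_label `"control"` or `"treated"` (or `NA` when not part of a
#'   comparison).
#' @param target_name Free-text protein name, e.g. `"p-Akt"` or `"HIF 1a"`.
#' @return An object of class `fluorescence_section`.
#' @export
fluorescence_section <- function(sample_id, edu, protein, pixel_size_um,
                                 group_label = NA_character_,
                                 target_name = NA_character_) {
  if (!is.matrix(edu) || !is.matrix(protein))
    stop_eduquant("channels must be matrices", "eduquant_validation_error")
  if (!identical(dim(edu), dim(protein)))
    stop_eduquant(sprintf(
      "channel shape mismatch in section '%s': edu %dx%d vs protein %dx%d",
      sample_id, nrow(edu), ncol(edu), nrow(protein), ncol(protein)),
      "eduquant_shape_error")
  if (min(edu) < 0 || min(protein) < 0)
    stop_eduquant("channel intensities must be non-negative",
                  "eduquant_validation_error")
  check_number(pixel_size_um, "pixel_size_um", 0, strict = TRUE)
  if (!is.na(group_label) && !group_label %in% c("control", "treated"))
    stop_eduquant("group_label must be 'control' or 'treated'",
                  "eduquant_validation_error")
  structure(list(
    sample_id = as.character(sample_id),
    channels = list(edu = edu, protein = protein),
    pixel_size_um = pixel_size_um,
    group_label = group_label,
    target_name = target_name
  ), class = "fluorescence_section")
}

#' @export
print.fluorescence_section <- function(x, ...) {
  d <- dim(x$channels$edu)
  cat(sprintf("fluorescence_section '%s': %d x %d px @ %g um/px, group %s, target %s\n",
              x$sample_id, d[1], d[2], x$pixel_size_um,
              x$group_label, x$target_name))
  invisible(x)
}

#' Binary compartment mask
#'
#' A binary mask aligned to a section, labelled by the compartment it
#' delimits: the EdU-defined `proliferating` area, its `non_proliferating`
#' complement within tissue, or the `tissue` support itself. The parameters
#' that produced the mask travel with it as provenance.
#'
#' @param grid Binary (0/1) matrix.
#' @param role One of `"proliferating"`, `"non_proliferating"`, `"tissue"`.
#' @param provenance Named list of the parameters used to produce the mask.
#' @return An object of class `area_mask`.
#' @export
area_mask <- function(grid, role = c("proliferating", "non_proliferating",
                                     "tissue"),
                      provenance = list()) {
  role <- match.arg(role)
  if (!is.matrix(grid))
    stop_eduquant("mask grid must be a matrix", "eduquant_validation_error")
  storage.mode(grid) <- "integer"
  if (!all(grid %in% c(0L, 1L)))
    stop_eduquant("mask grid must be binary", "eduquant_validation_error")
  structure(list(grid = grid, role = role, provenance = provenance),
            class = "area_mask")
}

#' @export
print.area_mask <- function(x, ...) {
  cat(sprintf("area_mask [%s]: %d x %d px, %d foreground px (%.1f%%)\n",
              x$role, nrow(x$grid), ncol(x$grid), sum(x$grid),
              100 * mean(x$grid)))
  invisible(x)
}

mask_area_mm2 <- function(mask_grid, pixel_size_um) {
  sum(mask_grid) * (pixel_size_um / 1000)^2
}
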