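# End-to-end orchestration: segment -> detect -> classify -> sample ROIs ->
# densities -> comparisons, with every artifact written to disk and every
# parameter and seed logged. The compartment call for the protein is made
# on the pooled control sections only and reused for treated sections:
# effective drugs can leave so little target expression that a
# per-treated-section call would be unstable.

pipeline_log <- function(lines, logfile = NULL, quiet = FALSE) {
  if (!quiet) message(paste(lines, collapse = "\n"))
  if (!is.null(logfile)) cat(lines, file = logfile, sep = "\n", append = TRUE)
  invisible(NULL)
}

#' Analyze a set of sections in memory
#'
#' The computational core of [run_pipeline()], operating on
#' [fluorescence_section()] objects directly (as produced by
#' [generate_experiment()] or [read_section()]).
#'
#' Stages: per-section proliferating-mask segmentation; blob detection on
#' both channels; one compartment call for the protein from the pooled
#' control-section detections; per-section circular ROI sampling (EdU ROIs
#' in the proliferating mask, protein ROIs in the called compartment) with
#' deterministic per-section seeds derived from the master seed; density
#' estimation; treated-vs-control comparison per readout.
#'
#' @param sections List of [fluorescence_section()]s with `group_label` set.
#' @param config Parameter list as from [default_config()] (the `samples` /
#'   file fields are ignored here); `config$seed` drives ROI sampling.
#' @param output_dir Optional directory; when given, all artifacts (masks,
#'   detection/ROI/density/comparison/call CSVs, report, provenance, log)
#'   are written there.
#' @param quiet Suppress progress messages.
#' @return A list of class `pipeline_result`: `report` (the
#'   [summarize_experiment()] table), `call`, `comparisons`, `densities`,
#'   `masks`, `detections`, `rois`.
#' @export
analyze_experiment <- function(sections, config = default_config(),
                               output_dir = NULL, quiet = TRUE) {
  if (length(sections) == 0L)
    stop_eduquant("no sections to analyze", "eduquant_validation_error")
  groups <- vapply(sections, function(s) s$group_label, character(1))
  if (anyNA(groups))
    stop_eduquant("every section needs a group_label for group comparison",
                  "eduquant_validation_error")
  ids <- vapply(sections, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids))
    stop_eduquant("duplicate sample ids", "eduquant_validation_error")
  sections <- sections[order(ids)]
  ids <- sort(ids)
  config <- merge_config(default_config(), config)  # fill missing params
  logfile <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    logfile <- file.path(output_dir, "pipeline.log")
    if (file.exists(logfile)) unlink(logfile)
  }
  seg <- config$segmentation; det <- config$detection
  loc <- config$localization; smp <- config$sampling
  qnt <- config$quantification
  master_seed <- config$seed %||% 1L
  pipeline_log(sprintf("eduquant pipeline: %d sections, master seed %d",
                       length(sections), master_seed), logfile, quiet)

  stage <- function(name, sample_id, expr) {
    tryCatch(expr, error = function(e) stop_eduquant(
      sprintf("stage '%s' failed for sample '%s': %s", name, sample_id,
              conditionMessage(e)),
      "eduquant_stage_error"))
  }

  masks <- list(); detections <- list()
  for (s in sections) {
    id <- s$sample_id
    tissue <- if (isTRUE(seg$tissue_detector)) stage("tissue", id,
      detect_tissue(s)) else NULL
    pmask <- stage("segment", id, segment_proliferating_area(
      s, smooth_sigma_px = seg$smooth_sigma_px, threshold = seg$threshold,
      hysteresis = seg$hysteresis,
      closing_radius_px = seg$closing_radius_px,
      min_region_area_px = seg$min_region_area_px))
    masks[[id]] <- stage("segment", id, derive_compartment_masks(pmask, tissue))
    detections[[id]] <- list(
      edu = stage("detect", id, detect_positive_cells(
        s, "edu", psf_sigma_px = det$psf_sigma_px,
        scale_factors = det$scale_factors,
        background_sigma_px = det$background_sigma_px,
        rel_threshold = det$rel_threshold, noise_k = det$noise_k,
        min_separation_px = det$min_separation_px)),
      protein = stage("detect", id, detect_positive_cells(
        s, "protein", psf_sigma_px = det$psf_sigma_px,
        scale_factors = det$scale_factors,
        background_sigma_px = det$background_sigma_px,
        rel_threshold = det$rel_threshold, noise_k = det$noise_k,
        min_separation_px = det$min_separation_px)))
    pipeline_log(sprintf(
      "  %s: proliferating %.1f%% of frame; %d EdU cells, %d protein cells",
      id, 100 * mean(masks[[id]]$proliferating$grid),
      nrow(detections[[id]]$edu$centroids),
      nrow(detections[[id]]$protein$centroids)), logfile, quiet)
  }

  # compartment call: pooled control-section protein detections
  ctrl_ids <- ids[groups[order(ids)] == "control"]
  if (length(ctrl_ids) == 0L)
    stop_eduquant("no control sections; compartment call impossible",
                  "eduquant_validation_error")
  inside <- 0L; total <- 0L
  for (id in ctrl_ids) {
    pts <- detections[[id]]$protein$centroids
    if (nrow(pts) == 0L) next
    inside <- inside + round(nrow(pts) * compute_overlap_fraction(
      pts, masks[[id]]$proliferating))
    total <- total + nrow(pts)
  }
  if (total == 0L)
    stop_eduquant("no protein detections in control sections; cannot classify compartment",
                  "eduquant_undefined_fraction_error")
  target_name <- sections[[1]]$target_name %||% config$target_name
  call <- classify_compartment(inside / total, low = loc$low, high = loc$high,
                               target_name = target_name, n_cells = total)
  protein_compartment <- call$call
  if (protein_compartment == "ambiguous") {
    if (is.null(config$compartment))
      stop_eduquant(sprintf(
        "ambiguous compartment call (overlap %.2f in [%.2f, %.2f]); set `compartment` to force one",
        call$overlap_fraction, loc$low, loc$high),
        "eduquant_ambiguous_call_error")
    protein_compartment <- config$compartment
  }
  if (!is.null(config$compartment)) protein_compartment <- config$compartment
  pipeline_log(sprintf(
    "  compartment call for %s: %s (overlap %.3f from %d pooled control cells)%s",
    target_name, call$call, call$overlap_fraction, total,
    if (!is.null(config$compartment))
      sprintf("; forced to %s", protein_compartment) else ""),
    logfile, quiet)

  densities <- list(); roi_tables <- list()
  for (i in seq_along(sections)) {
    s <- sections[[i]]; id <- s$sample_id
    for (channel in c("edu", "protein")) {
      comp <- if (channel == "edu") "proliferating" else protein_compartment
      roi_seed <- mix_seed(master_seed, i * 10L + (channel == "protein"))
      rois <- stage("sample", id, sample_circles(
        masks[[id]][[comp]], k = smp$k, radius_px = smp$radius_px,
        seed = roi_seed, area_fraction = smp$area_fraction,
        allow_overlap = !isFALSE(smp$allow_overlap)))
      densities[[paste(id, channel, sep = ":")]] <- stage("quantify", id,
        estimate_density(detections[[id]][[channel]], rois, s$pixel_size_um))
      roi_tables[[paste(id, channel, sep = ":")]] <-
        cbind(rois_to_df(rois, id), channel = channel,
              seed = roi_seed)
    }
  }

  comparisons <- list()
  for (channel in c("edu", "protein")) {
    pick <- function(grp) {
      keys <- paste(ids[groups[order(ids)] == grp], channel, sep = ":")
      densities[keys]
    }
    comparisons[[channel]] <- compare_groups(
      pick("control"), pick("treated"),
      n_boot = qnt$n_boot %||% 0L, seed = mix_seed(master_seed, 999L))
    pipeline_log(sprintf(
      "  %s readout [%s]: control %.1f vs treated %.1f cells/mm^2 -> %.1f%% change",
      if (channel == "edu") "proliferation" else "target",
      comparisons[[channel]]$compartment,
      comparisons[[channel]]$control_mean, comparisons[[channel]]$treated_mean,
      comparisons[[channel]]$percent_change), logfile, quiet)
  }

  report <- summarize_experiment(call, densities, comparisons)

  if (!is.null(output_dir)) {
    for (id in ids) {
      write_mask(masks[[id]]$proliferating,
                 file.path(output_dir, sprintf("%s_proliferating_mask.tif", id)))
      det_df <- do.call(rbind, lapply(c("edu", "protein"), function(ch)
        data.frame(sample_id = id, channel = ch,
                   detections[[id]][[ch]]$centroids)))
      write_table_csv(det_df,
                      file.path(output_dir, sprintf("%s_detections.csv", id)))
    }
    roi_df <- do.call(rbind, roi_tables)
    roi_df <- roi_df[order(roi_df$sample_id, roi_df$channel, roi_df$roi_id), ]
    rownames(roi_df) <- NULL
    write_table_csv(roi_df, file.path(output_dir, "rois.csv"))
    dens_df <- densities_to_df(densities)
    dens_df <- dens_df[order(dens_df$sample_id, dens_df$channel), ]
    rownames(dens_df) <- NULL
    write_table_csv(dens_df, file.path(output_dir, "densities.csv"))
    write_table_csv(comparisons_to_df(comparisons),
                    file.path(output_dir, "comparisons.csv"))
    write_calls(call, file.path(output_dir, "calls.csv"))
    write_table_csv(report, file.path(output_dir, "report.csv"))
    jsonlite::write_json(
      provenance_record(config, list(
        n_sections = length(sections),
        protein_compartment = protein_compartment)),
      file.path(output_dir, "provenance.json"), auto_unbox = TRUE,
      digits = NA, null = "null")
  }

  structure(list(report = report, call = call, comparisons = comparisons,
                 densities = densities, masks = masks,
                 detections = detections,
                 rois = if (length(roi_tables)) do.call(rbind, roi_tables)
                        else NULL,
                 protein_compartment = protein_compartment),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  print(x$call)
  for (cmp in x$comparisons) print(cmp)
  invisible(x)
}

#' Run the full pipeline from a configuration file
#'
#' Reads the config (see [read_config()]), loads every referenced section,
#' and runs [analyze_experiment()], writing all artifacts into `output_dir`.
#' Fully deterministic given the config: a rerun reproduces every artifact
#' byte for byte.
#'
#' @param config Path to a YAML config file, or an already-validated config
#'   list.
#' @param output_dir Artifact directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return The `pipeline_result`, invisibly.
#' @export
run_pipeline <- function(config, output_dir, quiet = FALSE) {
  cfg <- if (is.character(config)) read_config(config) else config
  sections <- lapply(cfg$samples, function(s) {
    if (is.null(s$protein)) {
      read_section(s$edu, NULL, cfg$pixel_size_um, sample_id = s$sample_id,
                   group_label = s$group, target_name = cfg$target_name,
                   channel_map = s$channel_map)
    } else {
      read_section(s$edu, s$protein, cfg$pixel_size_um,
                   sample_id = s$sample_id, group_label = s$group,
                   target_name = cfg$target_name)
    }
  })
  invisible(analyze_experiment(sections, cfg, output_dir = output_dir,
                               quiet = quiet))
}
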