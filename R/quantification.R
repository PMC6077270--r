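# Density estimation and group comparison: per-circle counts become
# cells/mm^2, per-sample means are averaged within experimental arms, and
# the efficacy statistic is the percent change of treated relative to
# control, 100 * (1 - treated/control).

#' Estimate cell density from circular ROI counts
#'
#' Counts every detection inside each circle (boundary-inclusive) and
#' converts the mean count to cells per square millimetre using the pixel
#' calibration: `circle_area_mm2 = pi * r^2 * (pixel_size_um / 1000)^2`.
#'
#' @param detections A `cell_detection_set` (or data.frame with `row`,
#'   `col`) for one section and channel.
#' @param rois List of `circular_roi` objects (all the same radius) from
#'   [sample_circles()].
#' @param pixel_size_um Micrometres per pixel.
#' @param sample_id,compartment,channel_role Optional metadata recorded in
#'   the estimate (inferred from the inputs when available).
#' @return A `density_estimate`: list with `sample_id`, `compartment`,
#'   `channel_role`, `counts` (per-circle), `circle_area_mm2`,
#'   `mean_density` (cells/mm^2) and `k`.
#' @export
estimate_density <- function(detections, rois, pixel_size_um,
                             sample_id = NULL, compartment = NULL,
                             channel_role = NULL) {
  if (length(rois) == 0L)
    stop_eduquant("at least one ROI is required", "eduquant_validation_error")
  radii <- vapply(rois, function(r) r$radius_px, numeric(1))
  if (max(radii) - min(radii) > 1e-9)
    stop_eduquant("ROIs have mixed radii; densities require a common circle area",
                  "eduquant_validation_error")
  check_number(pixel_size_um, "pixel_size_um", 0, strict = TRUE)
  if (radii[1] <= 0)
    stop_eduquant("zero-area circle", "eduquant_validation_error")
  counts <- vapply(rois, function(r) as.integer(count_in_circle(detections, r)),
                   integer(1))
  area_mm2 <- pi * radii[1]^2 * (pixel_size_um / 1000)^2
  if (is.null(sample_id) && inherits(detections, "cell_detection_set"))
    sample_id <- detections$section_id
  if (is.null(channel_role) && inherits(detections, "cell_detection_set"))
    channel_role <- detections$channel_role
  if (is.null(compartment)) compartment <- rois[[1]]$compartment
  structure(list(sample_id = sample_id %||% NA_character_,
                 compartment = compartment,
                 channel_role = channel_role %||% NA_character_,
                 counts = counts, circle_area_mm2 = area_mm2,
                 mean_density = mean(counts) / area_mm2,
                 k = length(counts)),
            class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf(
    "density_estimate '%s' [%s/%s]: %.1f cells/mm^2 (counts %s in %d circles of %.4g mm^2)\n",
    x$sample_id, x$channel_role, x$compartment, x$mean_density,
    paste(x$counts, collapse = ","), x$k, x$circle_area_mm2))
  invisible(x)
}

#' Compare treated against control densities
#'
#' Group means are means of per-sample densities (each section counts once);
#' the headline statistic is `percent_change = 100 * (1 - treated_mean /
#' control_mean)`. A treated increase yields a negative value. An optional
#' seeded nonparametric bootstrap over samples gives a percentile 95%
#' interval.
#'
#' @param control,treated Non-empty lists of `density_estimate` objects with
#'   matching channel and compartment.
#' @param n_boot Bootstrap replicates; 0 (default) disables the interval.
#' @param seed Bootstrap seed.
#' @return A `group_comparison`: list with `channel_role`, `compartment`,
#'   `control_mean`, `treated_mean`, `n_control`, `n_treated`,
#'   `percent_change` and optional `ci95`.
#' @export
compare_groups <- function(control, treated, n_boot = 0L, seed = 1L) {
  if (inherits(control, "density_estimate")) control <- list(control)
  if (inherits(treated, "density_estimate")) treated <- list(treated)
  if (length(control) == 0L || length(treated) == 0L)
    stop_eduquant("both groups need at least one density estimate",
                  "eduquant_validation_error")
  field <- function(lst, nm) vapply(lst, function(x) x[[nm]], character(1))
  chans <- unique(c(field(control, "channel_role"), field(treated, "channel_role")))
  comps <- unique(c(field(control, "compartment"), field(treated, "compartment")))
  if (length(chans) > 1L || length(comps) > 1L)
    stop_eduquant("density estimates mix channels or compartments",
                  "eduquant_validation_error")
  dens <- function(lst) vapply(lst, function(x) x$mean_density, numeric(1))
  dc <- dens(control); dt <- dens(treated)
  control_mean <- mean(dc); treated_mean <- mean(dt)
  if (control_mean <= 0)
    stop_eduquant("control mean density is zero; percent change is undefined",
                  "eduquant_undefined_comparison_error")
  pc <- 100 * (1 - treated_mean / control_mean)
  ci95 <- NULL
  if (n_boot > 0) {
    ci95 <- with_seed(seed, {
      reps <- vapply(seq_len(n_boot), function(i) {
        bc <- mean(dc[sample.int(length(dc), replace = TRUE)])
        bt <- mean(dt[sample.int(length(dt), replace = TRUE)])
        if (bc <= 0) NA_real_ else 100 * (1 - bt / bc)
      }, numeric(1))
      quantile(reps, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    })
  }
  structure(list(channel_role = chans, compartment = comps,
                 control_mean = control_mean, treated_mean = treated_mean,
                 n_control = length(dc), n_treated = length(dt),
                 percent_change = pc, ci95 = ci95, n_boot = n_boot),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "group_comparison [%s/%s]: control %.1f vs treated %.1f cells/mm^2 -> %.1f%% change (n = %d vs %d)\n",
    x$channel_role, x$compartment, x$control_mean, x$treated_mean,
    x$percent_change, x$n_control, x$n_treated))
  if (!is.null(x$ci95))
    cat(sprintf("  bootstrap 95%% CI: [%.1f, %.1f] (%d reps)\n",
                x$ci95[1], x$ci95[2], x$n_boot))
  invisible(x)
}

densities_to_df <- function(densities) {
  do.call(rbind, lapply(densities, function(d) data.frame(
    sample_id = d$sample_id, channel = d$channel_role,
    compartment = d$compartment, k = d$k,
    counts = paste(d$counts, collapse = ";"),
    circle_area_mm2 = d$circle_area_mm2,
    mean_density = d$mean_density)))
}

comparisons_to_df <- function(comparisons) {
  do.call(rbind, lapply(comparisons, function(x) data.frame(
    channel = x$channel_role, compartment = x$compartment,
    control_mean = x$control_mean, treated_mean = x$treated_mean,
    n_control = x$n_control, n_treated = x$n_treated,
    percent_change = x$percent_change)))
}

#' Assemble the experiment report table
#'
#' Combines per-sample densities, the compartment call and group comparisons
#' into one tidy table covering the two readouts of the method: EdU density
#' in the proliferating area (tumor proliferation) and protein density in
#' the protein's called compartment (target efficacy).
#'
#' @param calls `compartment_call` or list of them.
#' @param densities List of `density_estimate` objects.
#' @param comparisons List of `group_comparison` objects.
#' @return A data.frame with one row per density estimate plus one row per
#'   comparison (`record` column distinguishes `density` and `comparison`
#'   rows); empty inputs give an empty table with headers.
#' @export
summarize_experiment <- function(calls, densities, comparisons) {
  if (inherits(calls, "compartment_call")) calls <- list(calls)
  template <- data.frame(
    record = character(0), sample_id = character(0), channel = character(0),
    compartment = character(0), call = character(0), k = integer(0),
    mean_density = numeric(0), control_mean = numeric(0),
    treated_mean = numeric(0), percent_change = numeric(0))
  rows <- list()
  call_for <- function(channel) {
    if (channel == "protein" && length(calls) > 0) calls[[1]]$call
    else NA_character_
  }
  if (length(densities) > 0) {
    dd <- densities_to_df(densities)
    ids <- dd$sample_id
    if (anyNA(ids))
      stop_eduquant("density estimates without sample ids",
                    "eduquant_validation_error")
    rows$dens <- data.frame(
      record = "density", sample_id = dd$sample_id, channel = dd$channel,
      compartment = dd$compartment,
      call = vapply(dd$channel, call_for, character(1)),
      k = dd$k, mean_density = dd$mean_density,
      control_mean = NA_real_, treated_mean = NA_real_,
      percent_change = NA_real_)
  }
  if (length(comparisons) > 0) {
    cc <- comparisons_to_df(comparisons)
    rows$comp <- data.frame(
      record = "comparison", sample_id = NA_character_, channel = cc$channel,
      compartment = cc$compartment,
      call = vapply(cc$channel, call_for, character(1)),
      k = NA_integer_, mean_density = NA_real_,
      control_mean = cc$control_mean, treated_mean = cc$treated_mean,
      percent_change = cc$percent_change)
  }
  if (length(rows) == 0L) return(template)
  out <- do.call(rbind, rows)
  ord <- order(out$record, out$sample_id, out$channel, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
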