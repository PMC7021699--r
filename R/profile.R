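#' Describe a treatment condition
#'
#' Metadata container for the pretreatment applied to a sample:
#' electric-field intensity, pulse parameters and mechanical
#' compressions. Purely descriptive — it labels profiles and reports.
#'
#' @param label Condition label, e.g. `"control"` or `"PEF 5.5 kV/cm 5 us"`.
#' @param field_intensity Electric field in kV/cm.
#' @param pulse_duration Pulse duration in us.
#' @param n_pulses Number of pulses per burst.
#' @param repetition_period Pulse repetition period in ms.
#' @param n_compressions Mechanical compressions per cell.
#' @return A `treatment_condition` object.
#' @export
treatment_condition <- function(label,
                                field_intensity = 0,
                                pulse_duration = 0,
                                n_pulses = 0,
                                repetition_period = 0,
                                n_compressions = 0) {
  vals <- c(field_intensity, pulse_duration, n_pulses,
            repetition_period, n_compressions)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("treatment parameters must be non-negative")
  structure(list(label = as.character(label),
                 field_intensity = field_intensity,
                 pulse_duration = pulse_duration,
                 n_pulses = n_pulses,
                 repetition_period = repetition_period,
                 n_compressions = n_compressions),
            class = "treatment_condition")
}

#' @export
print.treatment_condition <- function(x, ...) {
  cat("Treatment:", x$label, "\n")
  cat(sprintf("  %g kV/cm, %g us x %g pulses (period %g ms), %g compressions\n",
              x$field_intensity, x$pulse_duration, x$n_pulses,
              x$repetition_period, x$n_compressions))
  invisible(x)
}

#' Background-normalized zone intensity profile of one cell
#'
#' Measures the mean dextran intensity in each equal-area zone of a
#' cell, plus the wall annulus, and normalizes each mean by the mean
#' extracellular background, giving dimensionless intensity ratios
#' (1 = as bright as the surrounding medium).
#'
#' @param dextran_channel 2-D intensity matrix.
#' @param zone_map A `zone_map` from [zonate()].
#' @param wall_mask Linear pixel indices of the wall annulus (e.g.
#'   `cell$wall`), or `NULL` to skip the wall ratio.
#' @param background A `background_estimate` (mean must be > 0).
#' @param label Cell label carried into the profile.
#' @return A `zone_profile`: list with `raw_means`, `ratios` (both
#'   length `n_zones`, zone 1 first), `wall_signal_ratio`,
#'   `background_mean` and `label`.
#' @export
profile_cell <- function(dextran_channel, zone_map, wall_mask, background,
                         label = NA_integer_) {
  stopifnot(inherits(zone_map, "zone_map"), is.matrix(dextran_channel))
  if (!is.list(background) || is.null(background$mean))
    stop("'background' must be a background_estimate")
  if (!is.finite(background$mean) || background$mean <= 0)
    stop("background mean must be > 0: normalization is undefined")
  nz <- zone_map$n_zones
  vals <- dextran_channel[zone_map$idx]
  raw <- vapply(seq_len(nz), function(k) mean(vals[zone_map$zone == k]),
                numeric(1))
  wall_ratio <- if (is.null(wall_mask) || length(wall_mask) == 0) NA_real_
    else mean(dextran_channel[wall_mask]) / background$mean
  structure(list(label = label,
                 raw_means = raw,
                 ratios = raw / background$mean,
                 wall_signal_ratio = wall_ratio,
                 background_mean = background$mean,
                 n_zones = nz),
            class = "zone_profile")
}

#' @export
print.zone_profile <- function(x, digits = 3, ...) {
  cat("Zone profile (cell ", x$label, "), ratios rim -> center:\n  ",
      paste(round(x$ratios, digits), collapse = " "), "\n", sep = "")
  if (!is.na(x$wall_signal_ratio))
    cat("  wall/background:", round(x$wall_signal_ratio, digits), "\n")
  invisible(x)
}

#' Segment, zonate and profile every cell of a scene
#'
#' Convenience pipeline: wall-channel segmentation, QC exclusion
#' filters, background estimation on the dextran channel, then one
#' background-normalized zone profile per passing cell.
#'
#' @param scene A `confocal_scene`, or a named list of channel matrices
#'   with at least `wall` and `dextran` (optionally `chlorophyll`).
#' @param pixel_size Pixel size in um/px (taken from the scene if
#'   present).
#' @param n_zones Zones per cell.
#' @param size_range,min_solidity QC limits, see
#'   [apply_exclusion_filters()].
#' @param background_margin Margin around cells for
#'   [estimate_background()], um.
#' @param use_chlorophyll Use the chlorophyll channel for multibody
#'   rejection when available.
#' @return List with `profiles` (list of `zone_profile`), `cells`
#'   (passing cells), `background` and `qc` (full QC table).
#' @export
profile_scene <- function(scene, pixel_size = NULL, n_zones = 10,
                          size_range = c(7, 13), min_solidity = 0.9,
                          background_margin = 2, use_chlorophyll = TRUE) {
  channels <- if (inherits(scene, "confocal_scene")) scene$channels else scene
  if (is.null(pixel_size))
    pixel_size <- if (inherits(scene, "confocal_scene")) scene$pixel_size else
      stop("'pixel_size' required when passing raw channels")
  if (is.null(channels$wall) || is.null(channels$dextran))
    stop("need 'wall' and 'dextran' channels")
  cells <- segment_cells(channels$wall, pixel_size)
  chl <- if (use_chlorophyll) channels$chlorophyll else NULL
  kept <- apply_exclusion_filters(cells, size_range = size_range,
                                  min_solidity = min_solidity,
                                  chlorophyll = chl)
  bg <- estimate_background(channels$dextran, cells, pixel_size,
                            margin = background_margin)
  profiles <- lapply(kept, function(cl) {
    zm <- zonate(cl, n_zones = n_zones)
    profile_cell(channels$dextran, zm, cl$wall, bg, label = cl$label)
  })
  list(profiles = profiles, cells = kept, background = bg,
       qc = attr(kept, "qc_table"))
}

#' Aggregate per-cell profiles into a treatment profile
#'
#' Per-zone arithmetic mean and sample (n-1) standard deviation over
#' cells, typically 10–20 cells per condition. Per-cell ratios are
#' retained for downstream statistical comparison.
#'
#' @param profiles List of `zone_profile`.
#' @param treatment A `treatment_condition` or a label string.
#' @param min_cells Minimum number of cells required (default 10).
#' @return A `treatment_profile`: `zone_mean`, `zone_sd`, `ratios`
#'   (cells x zones matrix), `wall_ratios`, `n_cells`, `treatment`.
#' @export
aggregate_treatment <- function(profiles, treatment, min_cells = 10) {
  n <- length(profiles)
  if (n < min_cells)
    stop("only ", n, " cell profiles; need at least ", min_cells,
         " (short by ", min_cells - n, ")")
  if (is.character(treatment)) treatment <- treatment_condition(treatment)
  nz <- profiles[[1]]$n_zones
  ratios <- t(vapply(profiles, function(p) p$ratios, numeric(nz)))
  wall <- vapply(profiles, function(p) p$wall_signal_ratio, numeric(1))
  structure(list(treatment = treatment,
                 n_cells = n,
                 zone_mean = colMeans(ratios),
                 zone_sd = apply(ratios, 2, stats::sd),
                 ratios = ratios,
                 wall_ratios = wall,
                 n_zones = nz),
            class = "treatment_profile")
}

#' @export
print.treatment_profile <- function(x, digits = 3, ...) {
  cat("Treatment profile: ", x$treatment$label, " (n = ", x$n_cells,
      " cells)\n", sep = "")
  tab <- rbind(mean = round(x$zone_mean, digits),
               sd = round(x$zone_sd, digits))
  colnames(tab) <- paste0("z", seq_len(x$n_zones))
  print(tab)
  if (any(is.finite(x$wall_ratios)))
    cat("  wall/background: mean", round(mean(x$wall_ratios, na.rm = TRUE), digits), "\n")
  invisible(x)
}

#' Tidy per-cell profile table
#'
#' @param profiles List of `zone_profile`.
#' @param treatment_label Label stored in the `treatment` column.
#' @return Data frame with columns `treatment`, `cell_label`, `zone`
#'   (1..n plus `"wall"`), `raw_mean`, `ratio` — ready for
#'   `write.csv()`.
#' @export
profiles_to_table <- function(profiles, treatment_label = "") {
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(
      treatment = treatment_label,
      cell_label = p$label,
      zone = c(as.character(seq_len(p$n_zones)), "wall"),
      raw_mean = c(p$raw_means, p$wall_signal_ratio * p$background_mean),
      ratio = c(p$ratios, p$wall_signal_ratio),
      stringsAsFactors = FALSE)
  }))
}

#' Bar plot of an aggregated zone profile
#'
#' Renders the per-zone mean normalized intensity with standard
#' deviation bars, rim (zone 1) to center (zone 10).
#'
#' @param x A `treatment_profile` or a list of them (plotted side by
#'   side).
#' @param ... Passed to [graphics::barplot()].
#' @export
plot_treatment_profile <- function(x, ...) {
  if (inherits(x, "treatment_profile")) x <- list(x)
  means <- t(vapply(x, function(tp) tp$zone_mean, numeric(x[[1]]$n_zones)))
  sds <- t(vapply(x, function(tp) tp$zone_sd, numeric(x[[1]]$n_zones)))
  labs <- vapply(x, function(tp) tp$treatment$label, character(1))
  bp <- graphics::barplot(means, beside = TRUE,
                          names.arg = paste0("z", seq_len(ncol(means))),
                          legend.text = labs,
                          xlab = "zone (rim → center)",
                          ylab = "intensity ratio vs background",
                          ylim = c(0, max(means + sds) * 1.1), ...)
  graphics::arrows(bp, means - sds, bp, means + sds,
                   angle = 90, code = 3, length = 0.02)
  invisible(bp)
}
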