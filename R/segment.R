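# Coerce EBImage Image results back to a plain matrix.
as_mat <- function(x) {
  if (inherits(x, "Image")) EBImage::imageData(x) else x
}

#' Segment cells from the wall-stain channel
#'
#' Detects cells as bright wall rings: Gaussian smoothing, Otsu
#' thresholding, hole-filling and connected-component labelling. Each
#' detected cell carries three masks: `outer` (filled ring, whole cell),
#' `wall` (thresholded annulus) and `inner` (cytoplasm: outer minus
#' wall, the single connected component containing the centroid). Zone
#' analysis downstream operates on the inner mask only, so the wall is
#' excluded from radial profiles. Cells touching the image border are
#' dropped (their zones would be incomplete).
#'
#' Thresholding: the wall ring is a narrow bright band on a dark
#' background, so after smoothing its half-maximum crossing is an
#' unbiased estimate of the band edges. The default `"halfmax"` method
#' thresholds midway between the background level (image median) and
#' the ring peak (0.999 intensity quantile). `"otsu"` is available but
#' on ring images — almost all pixels are background — it places the
#' threshold low and systematically widens the wall band by ~0.5 px,
#' biasing rim-zone intensities.
#'
#' @param wall_channel 2-D intensity matrix (wall stain, e.g. ConA).
#' @param pixel_size Pixel size in um/px.
#' @param sigma Gaussian smoothing sd in px before thresholding.
#' @param method Threshold method, `"halfmax"` (default) or `"otsu"`.
#' @return List of `segmented_cell` objects, each with pixel-index masks
#'   (`outer`, `inner`, `wall`), `centroid` (x, y in px),
#'   `equivalent_diameter` (um, from the outer mask area), `solidity`
#'   and `area_px`. Empty list if nothing is detected.
#' @export
segment_cells <- function(wall_channel, pixel_size, sigma = 2,
                          method = c("halfmax", "otsu")) {
  stopifnot(is.matrix(wall_channel), length(wall_channel) > 0, pixel_size > 0)
  method <- match.arg(method)
  rng <- range(wall_channel)
  if (diff(rng) == 0) {
    if (rng[1] > 0)
      warning("wall channel is constant (saturated?); nothing to segment")
    return(list())
  }
  sm <- as_mat(EBImage::gblur(wall_channel, sigma = sigma))
  th <- if (method == "halfmax") {
    bg <- stats::median(sm)
    peak <- stats::quantile(sm, 0.999, names = FALSE)
    (bg + peak) / 2
  } else {
    sm01 <- (sm - min(sm)) / (max(sm) - min(sm))
    min(sm) + EBImage::otsu(EBImage::Image(sm01)) * (max(sm) - min(sm))
  }
  annulus <- sm > th
  filled <- as_mat(EBImage::fillHull(annulus))
  lab <- as_mat(EBImage::bwlabel(filled))
  H <- nrow(lab); W <- ncol(lab)
  cells <- list()
  next_label <- 1L
  for (l in seq_len(max(lab))) {
    idx <- which(lab == l)
    if (length(idx) < 9) next  # speckle
    rows <- ((idx - 1L) %% H) + 1L
    cols <- ((idx - 1L) %/% H) + 1L
    if (any(rows == 1L | rows == H | cols == 1L | cols == W)) next  # border
    outer <- idx
    wall_idx <- idx[annulus[idx]]
    inner_cand <- matrix(FALSE, H, W)
    inner_cand[setdiff(idx, wall_idx)] <- TRUE
    centroid <- c(mean(cols), mean(rows))  # (x, y)
    inner <- integer(0)
    if (any(inner_cand)) {
      ilab <- as_mat(EBImage::bwlabel(inner_cand))
      cpix <- ilab[round(centroid[2]), round(centroid[1])]
      if (cpix == 0) {  # centroid on the wall; fall back to largest part
        tab <- tabulate(ilab[ilab > 0])
        cpix <- which.max(tab)
      }
      inner <- which(ilab == cpix)
    }
    wall_idx <- setdiff(outer, inner)  # mask algebra holds by construction
    cells[[next_label]] <- structure(list(
      label = next_label,
      outer = outer, inner = inner, wall = wall_idx,
      dim = c(H, W),
      centroid = centroid,
      area_px = length(outer),
      equivalent_diameter = 2 * sqrt(length(outer) / pi) * pixel_size,
      solidity = mask_solidity(rows, cols),
      pixel_size = pixel_size,
      qc_pass = NA, qc_reason = character(0)
    ), class = "segmented_cell")
    next_label <- next_label + 1L
  }
  cells
}

# Solidity = mask area / convex hull area, hull area counted in lattice
# pixels via Pick's theorem (shoelace area + boundary/2 + 1) so a perfect
# disk scores ~1 rather than >1.
mask_solidity <- function(rows, cols) {
  pts <- cbind(cols, rows)
  if (nrow(pts) < 4) return(1)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  nh <- nrow(hp)
  if (nh < 3) return(1)
  x <- hp[, 1]; y <- hp[, 2]
  a <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  per <- sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  min(1, nrow(pts) / (a + per / 2 + 1))
}

#' @export
print.segmented_cell <- function(x, ...) {
  cat(sprintf(
    "Segmented cell #%d: centroid (%.1f, %.1f) px, diameter %.2f um, solidity %.3f\n",
    x$label, x$centroid[1], x$centroid[2], x$equivalent_diameter, x$solidity))
  cat(sprintf("  masks: outer %d px, inner %d px, wall %d px\n",
              length(x$outer), length(x$inner), length(x$wall)))
  invisible(x)
}

#' QC exclusion filters for segmented cells
#'
#' Sorts out debris and exceptional individuals: cells outside the
#' expected equivalent-diameter range (`too_small` / `too_large`),
#' poorly convex objects such as fused doublets (`low_solidity`), and —
#' when a chlorophyll channel is supplied — connected components
#' containing more than one chlorophyll body (`multibody`).
#'
#' @param cells List of `segmented_cell` from [segment_cells()].
#' @param size_range Equivalent-diameter acceptance range in um;
#'   default 7–13 um, centered on the ~10 um cell size.
#' @param min_solidity Minimum solidity.
#' @param chlorophyll Optional chlorophyll channel matrix for multibody
#'   detection.
#' @return The passing cells, each with `qc_pass = TRUE`. The full QC
#'   table (all cells, pass flag, reason codes) is attached as attribute
#'   `"qc_table"`.
#' @export
apply_exclusion_filters <- function(cells, size_range = c(7, 13),
                                    min_solidity = 0.9,
                                    chlorophyll = NULL) {
  rows <- lapply(cells, function(cl) {
    reasons <- character(0)
    if (cl$equivalent_diameter < size_range[1]) reasons <- c(reasons, "too_small")
    if (cl$equivalent_diameter > size_range[2]) reasons <- c(reasons, "too_large")
    if (cl$solidity < min_solidity) reasons <- c(reasons, "low_solidity")
    if (!is.null(chlorophyll) && n_chl_bodies(cl, chlorophyll) > 1)
      reasons <- c(reasons, "multibody")
    cl$qc_pass <- length(reasons) == 0
    cl$qc_reason <- reasons
    cl
  })
  qc <- do.call(rbind, lapply(rows, function(cl) data.frame(
    label = cl$label,
    centroid_x = cl$centroid[1], centroid_y = cl$centroid[2],
    diameter_um = cl$equivalent_diameter, solidity = cl$solidity,
    qc_pass = cl$qc_pass,
    reason = paste(cl$qc_reason, collapse = ";"))))
  if (is.null(qc)) qc <- data.frame(label = integer(0), centroid_x = numeric(0),
                                    centroid_y = numeric(0), diameter_um = numeric(0),
                                    solidity = numeric(0), qc_pass = logical(0),
                                    reason = character(0))
  keep <- Filter(function(cl) isTRUE(cl$qc_pass), rows)
  attr(keep, "qc_table") <- qc
  keep
}

# Count distinct chlorophyll bodies inside a cell's outer mask.
n_chl_bodies <- function(cell, chlorophyll, min_area = 25) {
  m <- matrix(0, cell$dim[1], cell$dim[2])
  v <- chlorophyll[cell$outer]
  if (max(v) <= 0) return(0L)
  m[cell$outer] <- chlorophyll[cell$outer] > 0.5 * max(v)
  lab <- as_mat(EBImage::bwlabel(m))
  sizes <- tabulate(lab[lab > 0])
  sum(sizes >= min_area)
}

#' Estimate the extracellular background of the dextran channel
#'
#' Mean and sd over pixels farther than `margin` from every detected
#' cell — the "surrounding medium" reference used to normalize all zone
#' intensities.
#'
#' @param dextran_channel 2-D intensity matrix.
#' @param cells List of `segmented_cell` (their outer masks are excluded
#'   with the margin); may be empty.
#' @param pixel_size Pixel size in um/px.
#' @param margin Exclusion margin around each cell, um.
#' @param min_pixels Minimum background sample size.
#' @return A `background_estimate`: list with `mean`, `sd`, `n_pixels`.
#' @export
estimate_background <- function(dextran_channel, cells, pixel_size,
                                margin = 2, min_pixels = 100) {
  stopifnot(is.matrix(dextran_channel), pixel_size > 0)
  H <- nrow(dextran_channel); W <- ncol(dextran_channel)
  if (length(cells) == 0) {
    sel <- rep(TRUE, H * W)
  } else {
    occ <- matrix(FALSE, H, W)
    for (cl in cells) occ[cl$outer] <- TRUE
    dm <- as_mat(EBImage::distmap(matrix(as.numeric(!occ), H, W)))
    sel <- !occ & dm > margin / pixel_size
  }
  n <- sum(sel)
  if (n < min_pixels)
    stop("only ", n, " background pixels remain (need >= ", min_pixels,
         "); cells cover the field")
  v <- dextran_channel[sel]
  structure(list(mean = mean(v), sd = stats::sd(v), n_pixels = n),
            class = "background_estimate")
}

#' @export
print.background_estimate <- function(x, ...) {
  cat(sprintf("Background: mean %.3f, sd %.3f (n = %d px)\n",
              x$mean, x$sd, x$n_pixels))
  invisible(x)
}
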