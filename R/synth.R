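#' Specification of a synthetic confocal scene
#'
#' Describes a field of disk-shaped walled cells (about 10 um across by
#' default) suspended in a fluorescent dextran bath, to be rendered by
#' [generate_scene()]. Per cell, the dextran penetration mode is one of:
#'
#' * `"none"` — probe excluded from the whole cell (untreated control);
#' * `"wall_only"` — probe accumulates in the wall annulus but does not
#'   cross the plasma membrane;
#' * `"gradient"` — probe enters the cytoplasm with a radial gradient,
#'   brightest at the rim: \eqn{I(\rho) = B\,p\,e^{-(1-\rho)/\ell}} for
#'   normalized radius \eqn{\rho \in [0,1]}, emulating slow inward
#'   diffusion from freshly permeabilized membrane.
#'
#' @param image_shape Integer (H, W) in pixels.
#' @param pixel_size Pixel size in um/px. Default 0.1 so a 10 um cell
#'   spans ~100 px.
#' @param n_cells Number of cells to place (0 allowed).
#' @param cell_radius_mean,cell_radius_sd Outer cell radius in um.
#' @param wall_thickness Wall annulus thickness in um.
#' @param background_level Extracellular dextran intensity B (a.u.).
#' @param penetration_mode Single mode or vector of length `n_cells`.
#' @param gradient_params List with `rim_ratio` (p, in \[0,1\]) and
#'   `decay_length` (l, normalized radius units, > 0).
#' @param wall_dextran_ratio Dextran accumulation level in the wall
#'   annulus relative to background, for `wall_only` cells (a gradient
#'   cell's annulus carries the rim value `rim_ratio * B` instead, and a
#'   control cell's wall holds no probe).
#' @param noise_params List with `photon_scale` (Poisson counts per
#'   intensity unit; 0 disables shot noise) and `read_sd` (Gaussian read
#'   noise sd, a.u.; 0 disables).
#' @param min_gap Minimum edge-to-edge distance between cells, um.
#' @param seed Integer seed; identical specs render bit-identical scenes.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(image_shape = c(900L, 900L),
                       pixel_size = 0.1,
                       n_cells = 15,
                       cell_radius_mean = 5,
                       cell_radius_sd = 0.25,
                       wall_thickness = 0.8,
                       background_level = 100,
                       penetration_mode = "gradient",
                       gradient_params = list(rim_ratio = 0.8, decay_length = 0.5),
                       wall_dextran_ratio = 3,
                       noise_params = list(photon_scale = 4, read_sd = 2),
                       min_gap = 1.5,
                       seed = 1L) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 16),
            pixel_size > 0, n_cells >= 0,
            cell_radius_mean > 0, cell_radius_sd >= 0,
            wall_thickness > 0, wall_thickness < cell_radius_mean,
            background_level >= 0, wall_dextran_ratio >= 0, min_gap >= 0)
  p <- gradient_params$rim_ratio
  l <- gradient_params$decay_length
  if (is.null(p) || p < 0 || p > 1)
    stop("gradient_params$rim_ratio must lie in [0, 1]")
  if (is.null(l) || l <= 0)
    stop("gradient_params$decay_length must be > 0")
  if (is.null(noise_params$photon_scale) || noise_params$photon_scale < 0 ||
      is.null(noise_params$read_sd) || noise_params$read_sd < 0)
    stop("noise_params must give non-negative photon_scale and read_sd")
  mode <- rep_len(as.character(penetration_mode), max(n_cells, 1L))
  if (!all(mode %in% c("none", "wall_only", "gradient")))
    stop("penetration_mode must be 'none', 'wall_only' or 'gradient'")
  spec <- list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
               n_cells = as.integer(n_cells),
               cell_radius_mean = cell_radius_mean,
               cell_radius_sd = cell_radius_sd,
               wall_thickness = wall_thickness,
               background_level = background_level,
               penetration_mode = if (n_cells > 0) mode[seq_len(n_cells)] else character(),
               gradient_params = list(rim_ratio = p, decay_length = l),
               wall_dextran_ratio = wall_dextran_ratio,
               noise_params = noise_params,
               min_gap = min_gap, seed = as.integer(seed))
  class(spec) <- "scene_spec"
  spec
}

#' Expected noiseless zone profile of the radial gradient model
#'
#' Closed-form per-zone means of the normalized intracellular intensity
#' \eqn{I(\rho)/B = p\,e^{-(1-\rho)/\ell}} over exact equal-area annuli.
#' Zone k (outside-in) spans \eqn{\rho \in [\sqrt{(n-k)/n}, \sqrt{(n-k+1)/n}]}.
#' This is the analytic oracle against which pipeline-measured profiles
#' are validated.
#'
#' @param rim_ratio p, intensity at the rim relative to background.
#' @param decay_length l, decay length in normalized radius units.
#' @param n_zones Number of equal-area zones (default 10).
#' @param mode Penetration mode; `"none"` and `"wall_only"` give zeros.
#' @return Numeric vector of length `n_zones`, zone 1 (rim) first.
#' @export
expected_zone_profile <- function(rim_ratio, decay_length, n_zones = 10,
                                  mode = "gradient") {
  stopifnot(n_zones >= 1, rim_ratio >= 0, rim_ratio <= 1, decay_length > 0)
  if (mode %in% c("none", "wall_only")) return(rep(0, n_zones))
  k <- seq_len(n_zones)
  s1 <- sqrt((n_zones - k) / n_zones)      # inner rho bound of zone k
  s2 <- sqrt((n_zones - k + 1) / n_zones)  # outer rho bound
  l <- decay_length
  # area mean over the annulus: n * int_{s1}^{s2} 2 rho p e^{(rho-1)/l} drho
  if (l > 1e6) {
    # flat-profile regime: first-order expansion in 1/l avoids the
    # catastrophic cancellation of the closed form
    rim_ratio * (1 + n_zones / l *
                   (2 * (s2^3 - s1^3) / 3 - (s2^2 - s1^2)))
  } else {
    # antiderivative 2 l e^{(rho-1)/l} (rho - l), grouped via expm1
    du <- (s2 - s1) / l
    bracket <- (s2 - l) * expm1(du) + (s2 - s1)
    rim_ratio * n_zones * 2 * l * exp((s1 - 1) / l) * bracket
  }
}

# Truncated-normal draw of cell radii (um), bounded away from zero.
draw_radii <- function(n, mean, sd, wall) {
  lo <- max(wall * 1.5, mean - 3 * sd)
  hi <- mean + 3 * sd
  r <- stats::rnorm(n, mean, sd)
  pmin(pmax(r, lo), hi)
}

# Non-overlapping placement by rejection sampling. Returns data.frame of
# centers (px) or errors after max_attempts per cell.
place_cells <- function(spec, max_attempts = 5000L) {
  n <- spec$n_cells
  H <- spec$image_shape[1]; W <- spec$image_shape[2]
  r_um <- draw_radii(n, spec$cell_radius_mean, spec$cell_radius_sd,
                     spec$wall_thickness)
  r_px <- r_um / spec$pixel_size
  gap_px <- spec$min_gap / spec$pixel_size
  cx <- cy <- numeric(0)
  for (i in seq_len(n)) {
    m <- 2 * r_px[i]  # cell edge at least one radius inside the frame
    if (2 * m >= W || 2 * m >= H)
      stop("image too small to place a cell of radius ", round(r_px[i]), " px")
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      x <- stats::runif(1, m, W - m)
      y <- stats::runif(1, m, H - m)
      if (i == 1L ||
          all(sqrt((cx - x)^2 + (cy - y)^2) >= r_px[i] + r_px[seq_len(i - 1)] + gap_px)) {
        ok <- TRUE; break
      }
    }
    if (!ok)
      stop("cell placement failed after ", max_attempts,
           " attempts (cell ", i, " of ", n, "); reduce n_cells or enlarge the image")
    cx <- c(cx, x); cy <- c(cy, y)
  }
  data.frame(center_x = cx, center_y = cy,
             radius_px = r_px, radius_um = r_um,
             mode = spec$penetration_mode, stringsAsFactors = FALSE)
}

#' Render noiseless channels for an explicit cell table
#'
#' Low-level renderer behind [generate_scene()], exposed so that
#' deliberately pathological layouts (border-touching cells, fused
#' doublets) can be rendered for validation. Disk edges are anti-aliased
#' by 2x2 subpixel sampling. Cells are composited in table order; for
#' overlapping cells the later entry wins where it covers.
#'
#' @param cells Data frame with columns `center_x`, `center_y`,
#'   `radius_px` (outer radius) and `mode`.
#' @param image_shape Integer (H, W) in pixels.
#' @param wall_px Wall annulus thickness in px.
#' @param background_level Extracellular dextran level B.
#' @param gradient_params As in [scene_spec()].
#' @param wall_dextran_ratio As in [scene_spec()].
#' @param levels Intensity levels (a.u.) for the stain channels.
#' @return Named list of H x W matrices: `wall`, `dextran`,
#'   `chlorophyll`, `transmission`.
#' @export
render_scene <- function(cells, image_shape, wall_px,
                         background_level = 100,
                         gradient_params = list(rim_ratio = 0.8, decay_length = 0.5),
                         wall_dextran_ratio = 3,
                         levels = list(wall = 150, chlorophyll = 120,
                                       transmission_bg = 200, transmission_cell = 140)) {
  H <- image_shape[1]; W <- image_shape[2]
  B <- background_level
  wall_ch <- matrix(0, H, W)
  dex_ch <- matrix(B, H, W)
  chl_ch <- matrix(0, H, W)
  trn_ch <- matrix(levels$transmission_bg, H, W)
  p <- gradient_params$rim_ratio
  l <- gradient_params$decay_length
  off <- c(-0.25, 0.25)  # 2x supersampling offsets
  for (i in seq_len(nrow(cells))) {
    cxy <- c(cells$center_x[i], cells$center_y[i])
    ro <- cells$radius_px[i]
    ri <- ro - wall_px
    if (ri <= 1) stop("wall thicker than cell radius")
    mode <- cells$mode[i]
    y0 <- max(1L, floor(cxy[2] - ro - 2)); y1 <- min(H, ceiling(cxy[2] + ro + 2))
    x0 <- max(1L, floor(cxy[1] - ro - 2)); x1 <- min(W, ceiling(cxy[1] + ro + 2))
    ys <- y0:y1; xs <- x0:x1
    ny <- length(ys); nx <- length(xs)
    f_in <- f_wall <- f_out <- dex_in <- matrix(0, ny, nx)
    for (dy in off) for (dx in off) {
      r <- sqrt(outer((ys + dy - cxy[2])^2, (xs + dx - cxy[1])^2, `+`))
      inside <- r < ri
      wallb <- r >= ri & r < ro
      f_in <- f_in + inside
      f_wall <- f_wall + wallb
      f_out <- f_out + (r >= ro)
      if (mode == "gradient") {
        val <- B * p * exp(-(1 - pmin(r / ri, 1)) / l)
        dex_in <- dex_in + val * inside
      }
    }
    f_in <- f_in / 4; f_wall <- f_wall / 4; f_out <- f_out / 4; dex_in <- dex_in / 4
    # wall-annulus dextran: accumulation only in the wall-blocked mode;
    # in gradient mode the annulus carries the rim value (continuous
    # across the membrane), in the control mode nothing is in the wall
    wall_dex <- switch(mode,
                       none = 0,
                       wall_only = wall_dextran_ratio * B,
                       gradient = B * p)
    dex_new <- dex_ch[ys, xs] * f_out + dex_in + f_wall * wall_dex
    dex_ch[ys, xs] <- dex_new
    wall_ch[ys, xs] <- pmax(wall_ch[ys, xs], f_wall * levels$wall)
    chl_ch[ys, xs] <- pmax(chl_ch[ys, xs], f_in * levels$chlorophyll)
    trn_ch[ys, xs] <- trn_ch[ys, xs] * f_out +
      (1 - f_out) * levels$transmission_cell
  }
  list(wall = wall_ch, dextran = dex_ch, chlorophyll = chl_ch,
       transmission = trn_ch)
}

apply_detector_noise <- function(m, photon_scale, read_sd) {
  if (photon_scale > 0)
    m[] <- stats::rpois(length(m), pmax(m, 0) * photon_scale) / photon_scale
  if (read_sd > 0)
    m[] <- m + stats::rnorm(length(m), 0, read_sd)
  m
}

#' Generate a synthetic multi-channel confocal scene with ground truth
#'
#' Places non-overlapping cells (rejection sampling), renders the four
#' channels (wall stain, dextran, chlorophyll autofluorescence,
#' transmission), then applies Poisson shot noise and Gaussian read
#' noise. The same `scene_spec` (including seed) always yields
#' bit-identical pixel data.
#'
#' @param spec A [scene_spec()].
#' @return A `confocal_scene`: list with `channels` (named list of H x W
#'   matrices), `pixel_size`, `spec` and `ground_truth` (cell table,
#'   per-cell expected noiseless zone profiles, background level, seed).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$seed, {
    cells <- if (spec$n_cells > 0) place_cells(spec) else
      data.frame(center_x = numeric(0), center_y = numeric(0),
                 radius_px = numeric(0), radius_um = numeric(0),
                 mode = character(0), stringsAsFactors = FALSE)
    wall_px <- spec$wall_thickness / spec$pixel_size
    channels <- render_scene(cells, spec$image_shape, wall_px,
                             background_level = spec$background_level,
                             gradient_params = spec$gradient_params,
                             wall_dextran_ratio = spec$wall_dextran_ratio)
    channels <- lapply(channels, apply_detector_noise,
                       photon_scale = spec$noise_params$photon_scale,
                       read_sd = spec$noise_params$read_sd)
  })
  cells$inner_radius_px <- cells$radius_px - wall_px
  expected <- t(vapply(seq_len(nrow(cells)), function(i)
    expected_zone_profile(spec$gradient_params$rim_ratio,
                          spec$gradient_params$decay_length,
                          n_zones = 10, mode = cells$mode[i]),
    numeric(10)))
  if (nrow(cells) == 0) expected <- matrix(numeric(0), 0, 10)
  out <- list(channels = channels,
              pixel_size = spec$pixel_size,
              spec = spec,
              ground_truth = list(cells = cells,
                                  expected_profiles = expected,
                                  background_level = spec$background_level,
                                  seed = spec$seed))
  class(out) <- "confocal_scene"
  out
}

#' @export
print.confocal_scene <- function(x, ...) {
  d <- dim(x$channels$dextran)
  cat("Synthetic confocal scene: ", d[1], "x", d[2], " px (",
      x$pixel_size, " um/px), ", nrow(x$ground_truth$cells), " cells\n", sep = "")
  if (nrow(x$ground_truth$cells) > 0)
    cat("  modes:", paste(sprintf("%s (%d)",
        names(table(x$ground_truth$cells$mode)),
        as.integer(table(x$ground_truth$cells$mode))), collapse = ", "), "\n")
  invisible(x)
}

#' Write/read a scene as multi-channel TIFF plus JSON ground truth
#'
#' Channels are stored in the order wall, dextran, chlorophyll,
#' transmission as 16-bit planes (intensities rounded to integer a.u.).
#'
#' @param scene A `confocal_scene`.
#' @param path TIFF file path.
#' @param truth_path Optional JSON sidecar path for the ground truth.
#' @return `write_scene` returns `path` invisibly; `read_scene` returns
#'   a `confocal_scene` (without spec, and with ground truth only if the
#'   sidecar is given).
#' @export
write_scene <- function(scene, path, truth_path = NULL) {
  stopifnot(inherits(scene, "confocal_scene"))
  planes <- lapply(scene$channels[c("wall", "dextran", "chlorophyll",
                                    "transmission")],
                   function(m) pmin(pmax(round(m), 0), 65535) / 65535)
  tiff::writeTIFF(planes, path, bits.per.sample = 16L)
  if (!is.null(truth_path)) {
    gt <- scene$ground_truth
    jsonlite::write_json(
      list(pixel_size = scene$pixel_size,
           background_level = gt$background_level,
           seed = gt$seed,
           cells = gt$cells,
           expected_profiles = gt$expected_profiles),
      truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_scene
#' @param pixel_size Pixel size in um/px (overridden by the sidecar).
#' @export
read_scene <- function(path, truth_path = NULL, pixel_size = 0.1) {
  planes <- tiff::readTIFF(path, all = TRUE)
  if (length(planes) != 4)
    stop("expected a 4-plane TIFF (wall, dextran, chlorophyll, transmission)")
  channels <- lapply(planes, function(m) m * 65535)
  names(channels) <- c("wall", "dextran", "chlorophyll", "transmission")
  ground_truth <- NULL
  if (!is.null(truth_path)) {
    gt <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    pixel_size <- gt$pixel_size
    ground_truth <- list(cells = as.data.frame(gt$cells),
                         expected_profiles = gt$expected_profiles,
                         background_level = gt$background_level,
                         seed = gt$seed)
  }
  out <- list(channels = channels, pixel_size = pixel_size,
              spec = NULL, ground_truth = ground_truth)
  class(out) <- "confocal_scene"
  out
}
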