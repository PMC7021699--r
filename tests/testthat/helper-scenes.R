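# Shared fixtures: scenes and masks are always built in code at test time.

# Standard study scene: 15 cells of ~10 um at default noise.
study_scene <- function(mode, seed, noiseless = FALSE, n_cells = 15) {
  np <- if (noiseless) list(photon_scale = 0, read_sd = 0)
        else list(photon_scale = 4, read_sd = 2)
  generate_scene(scene_spec(n_cells = n_cells, penetration_mode = mode,
                            noise_params = np, seed = seed))
}

# Small single-cell scene for cheap unit tests.
one_cell_scene <- function(mode = "gradient", seed = 1, noiseless = TRUE, ...) {
  np <- if (noiseless) list(photon_scale = 0, read_sd = 0)
        else list(photon_scale = 4, read_sd = 2)
  generate_scene(scene_spec(image_shape = c(256L, 256L), n_cells = 1,
                            penetration_mode = mode, noise_params = np,
                            seed = seed, ...))
}

# Logical disk mask (pixel centers within radius R of the center).
disk_mask <- function(R, pad = 4) {
  n <- 2 * (R + pad) + 1
  ctr <- R + pad + 1
  r2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`)
  r2 <= R^2
}

# Aggregate a scene's cell profiles under one label.
scene_profile <- function(scene, label, min_cells = 10) {
  res <- profile_scene(scene)
  aggregate_treatment(res$profiles, label, min_cells = min_cells)
}

# Fabricate a zone_profile without running the image pipeline.
fake_profile <- function(ratios, wall = NA_real_, label = 1L, bg = 100) {
  structure(list(label = label, raw_means = ratios * bg, ratios = ratios,
                 wall_signal_ratio = wall, background_mean = bg,
                 n_zones = length(ratios)),
            class = "zone_profile")
}

# Fabricate a treatment_profile from a cells x zones ratio matrix.
fake_treatment <- function(ratios, label = "t", wall_ratios = NULL) {
  if (is.null(wall_ratios)) wall_ratios <- rep(NA_real_, nrow(ratios))
  structure(list(treatment = treatment_condition(label),
                 n_cells = nrow(ratios),
                 zone_mean = colMeans(ratios),
                 zone_sd = apply(ratios, 2, stats::sd),
                 ratios = ratios, wall_ratios = wall_ratios,
                 n_zones = ncol(ratios)),
            class = "treatment_profile")
}

# Fabricate a penetration_call with just the fields inference needs.
fake_call <- function(probe, entered, wall = FALSE, treatment = "t") {
  structure(list(treatment = treatment, probe = probe,
                 entered_cytoplasm = entered, entered_wall = wall,
                 score = NA_real_, wall_score = NA_real_, p_value = NA_real_),
            class = "penetration_call")
}

table1_ladder <- function() build_ladder(c(3000, 10000, 40000, 70000))
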