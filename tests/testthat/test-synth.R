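test_that("identical scene specs render bit-identical scenes", {
  sp <- scene_spec(image_shape = c(320L, 320L), n_cells = 2, seed = 11)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a$channels, b$channels)
  expect_identical(a$ground_truth, b$ground_truth)
  sp2 <- scene_spec(image_shape = c(320L, 320L), n_cells = 2, seed = 12)
  expect_false(identical(generate_scene(sp2)$channels$dextran,
                         a$channels$dextran))
})

test_that("an empty scene is background everywhere", {
  sp <- scene_spec(image_shape = c(128L, 128L), n_cells = 0,
                   noise_params = list(photon_scale = 0, read_sd = 0),
                   seed = 1)
  sc <- generate_scene(sp)
  expect_equal(nrow(sc$ground_truth$cells), 0)
  expect_true(all(sc$channels$dextran == 100))
  expect_true(all(sc$channels$wall == 0))
  # with noise the mean stays at background level
  spn <- scene_spec(image_shape = c(128L, 128L), n_cells = 0, seed = 1)
  dx <- generate_scene(spn)$channels$dextran
  expect_lt(abs(mean(dx) - 100), 0.5)
})

test_that("noiseless dextran outside all cells is exactly background", {
  sc <- one_cell_scene("gradient", seed = 3)
  gt <- sc$ground_truth$cells
  H <- nrow(sc$channels$dextran)
  rows <- row(sc$channels$dextran); cols <- col(sc$channels$dextran)
  r <- sqrt((rows - gt$center_y)^2 + (cols - gt$center_x)^2)
  outside <- r > gt$radius_px + 1.5
  expect_true(all(sc$channels$dextran[outside] == 100))
})

test_that("cell placement respects margins and fails loudly when infeasible", {
  sc <- study_scene("none", seed = 5, noiseless = TRUE, n_cells = 5)
  gt <- sc$ground_truth$cells
  H <- sc$spec$image_shape[1]; W <- sc$spec$image_shape[2]
  # frame margin: at least one radius between cell edge and border
  expect_true(all(gt$center_x - 2 * gt$radius_px >= 0))
  expect_true(all(gt$center_x + 2 * gt$radius_px <= W))
  expect_true(all(gt$center_y - 2 * gt$radius_px >= 0))
  expect_true(all(gt$center_y + 2 * gt$radius_px <= H))
  # pairwise non-overlap
  d <- as.matrix(dist(gt[, c("center_x", "center_y")]))
  sep <- outer(gt$radius_px, gt$radius_px, `+`)
  expect_true(all(d[upper.tri(d)] > sep[upper.tri(sep)]))
  # infeasible: too many large cells in a tiny frame
  expect_error(generate_scene(scene_spec(image_shape = c(128L, 128L),
                                         n_cells = 10, seed = 1)),
               "placement|too small")
})

test_that("expected zone profile matches numerical quadrature", {
  # independent oracle: area-weighted numerical integration per zone
  quad_profile <- function(p, l, n = 10) {
    vapply(seq_len(n), function(k) {
      s1 <- sqrt((n - k) / n); s2 <- sqrt((n - k + 1) / n)
      stats::integrate(function(rho) 2 * rho * p * exp(-(1 - rho) / l),
                       s1, s2, rel.tol = 1e-12)$value * n
    }, numeric(1))
  }
  for (par in list(c(0.8, 0.5), c(1, 0.1), c(0.3, 2), c(0.95, 0.05)))
    expect_equal(expected_zone_profile(par[1], par[2]),
                 quad_profile(par[1], par[2]), tolerance = 1e-9)
})

test_that("expected zone profile limits and monotonicity", {
  expect_equal(expected_zone_profile(0, 0.5), rep(0, 10))
  expect_equal(expected_zone_profile(0.5, 0.5, mode = "none"), rep(0, 10))
  expect_equal(expected_zone_profile(0.5, 0.5, mode = "wall_only"), rep(0, 10))
  # flat limit: infinite decay length leaves the rim ratio everywhere
  expect_equal(expected_zone_profile(1, 1e9), rep(1, 10), tolerance = 1e-6)
  expect_equal(expected_zone_profile(0.8, 1e12), rep(0.8, 10), tolerance = 1e-6)
  # gradient decreases strictly from rim to center
  prof <- expected_zone_profile(0.8, 0.5)
  expect_true(all(diff(prof) < 0))
})

test_that("ground truth expected profiles follow each cell's mode", {
  sc <- generate_scene(scene_spec(image_shape = c(700L, 700L), n_cells = 3,
                                  penetration_mode = c("none", "gradient",
                                                       "wall_only"),
                                  seed = 21))
  gt <- sc$ground_truth
  expect_equal(gt$cells$mode, c("none", "gradient", "wall_only"))
  expect_equal(gt$expected_profiles[1, ], rep(0, 10))
  expect_equal(gt$expected_profiles[3, ], rep(0, 10))
  expect_true(all(diff(gt$expected_profiles[2, ]) < 0))
})

test_that("scene TIFF + JSON sidecar round-trips", {
  sc <- one_cell_scene("gradient", seed = 4)
  tp <- withr::local_tempfile(fileext = ".tif")
  jp <- withr::local_tempfile(fileext = ".json")
  write_scene(sc, tp, truth_path = jp)
  back <- read_scene(tp, truth_path = jp)
  # 16-bit integer storage: exact after rounding
  expect_equal(round(back$channels$dextran), round(sc$channels$dextran))
  expect_equal(back$pixel_size, sc$pixel_size)
  expect_equal(as.numeric(back$ground_truth$cells$radius_px),
               sc$ground_truth$cells$radius_px)
})

test_that("scene spec validation rejects bad parameters", {
  expect_error(scene_spec(gradient_params = list(rim_ratio = 1.2,
                                                 decay_length = 0.5)))
  expect_error(scene_spec(gradient_params = list(rim_ratio = 0.5,
                                                 decay_length = 0)))
  expect_error(scene_spec(penetration_mode = "sideways"))
  expect_error(scene_spec(background_level = -5))
  expect_error(scene_spec(noise_params = list(photon_scale = -1, read_sd = 0)))
})
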