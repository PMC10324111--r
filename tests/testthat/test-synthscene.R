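# Synthetic scene generator: rendering contracts, composition, determinism.

test_that("spot profile hits its anchor intensities and is radially monotone", {
  h <- 101; wdt <- 101
  ctr <- c(51, 51)
  f <- render_spot(ctr, 30, peak = 250, edge = 130, h, wdt)
  expect_equal(f[51, 51], 250)
  # value at exactly r = d/2 equals the edge intensity
  expect_equal(stemspot:::bilinear_sample(f, 51, 51 + 15), 130, tolerance = 1e-6)
  # brute-force sampling: radial profile monotone non-increasing, zero tail
  rad <- seq(0, 30, length.out = 100)
  prof <- stemspot:::bilinear_sample(f, rep(51, 100), 51 + rad)
  expect_true(all(diff(prof) <= 1e-9))
  # zero contribution beyond 1.5x the radius, checked on the raw field
  rho <- sqrt(outer(seq_len(h) - 51, seq_len(wdt) - 51, function(r, c) r^2 + c^2))
  expect_true(all(f[rho >= 1.5 * 15] == 0))
  expect_error(render_spot(ctr, 2.5, 250, 130, h, wdt),
               class = "stemspot_parameter_error")
})

test_that("scene composition is exact when all perturbations are off", {
  sc <- clean_scene()
  p <- sc$truth$params
  # inside the trunk band, away from the spot, intensity equals the trunk level
  cols <- sc$truth$trunk_cols[1]:sc$truth$trunk_cols[2]
  band <- sc$image[, cols]
  spot_dist <- sqrt(outer((seq_len(nrow(band))) - p$spot_centroid[1],
                          cols - p$spot_centroid[2],
                          function(r, c) r^2 + c^2))
  expect_true(all(band[spot_dist > (0.75 * p$spot_diameter_px)^2] == p$trunk_intensity))
  # outside the band: background
  expect_true(all(sc$image[, 1:(min(cols) - 1)] == p$background_intensity))
  # centroid pixel carries the peak
  expect_equal(sc$image[p$spot_centroid[1], p$spot_centroid[2]],
               p$spot_peak_intensity)
})

test_that("scenes are bit-identical under identical (params, seed)", {
  p <- scene_params(seed = 99)
  s1 <- generate_scene(p)
  s2 <- generate_scene(p)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$trunk_mask, s2$trunk_mask)
})

test_that("mask alphabet, dimensions and truth echo hold on every scene", {
  ds <- generate_dataset(12, seed = 3)
  for (sc in ds$scenes) {
    expect_setequal(unique(as.vector(sc$trunk_mask)), c(0, 255))
    expect_identical(dim(sc$image), dim(sc$trunk_mask))
    expect_true(all(sc$image >= 0 & sc$image <= 255))
    p <- sc$truth$params
    expect_equal(sc$truth$true_width_at_spot_row, p$trunk_width_px)
    # spot entirely inside the trunk band
    expect_lte(abs(p$spot_centroid[2] - p$trunk_center_col_px) +
                 p$spot_diameter_px / 2, p$trunk_width_px / 2)
  }
})

test_that("parameter invariants are enforced with named errors", {
  expect_error(scene_params(spot_centroid = c(135, 460)),
               "inside the trunk band", class = "stemspot_parameter_error")
  expect_error(scene_params(spot_peak_intensity = 120, spot_edge_intensity = 140),
               class = "stemspot_parameter_error")
  expect_error(scene_params(spot_edge_intensity = 30),
               class = "stemspot_parameter_error")
  expect_error(scene_params(noise_sigma = -1), class = "stemspot_parameter_error")
})

test_that("dataset generation is deterministic and respects requested ranges", {
  d1 <- generate_dataset(50, seed = 7)
  d2 <- generate_dataset(50, seed = 7)
  expect_identical(d1$manifest, d2$manifest)
  expect_equal(nrow(d1$manifest), 50)

  d3 <- generate_dataset(200, list(trunk_width_px = c(80, 120)), seed = 8)
  expect_true(all(d3$manifest$trunk_width_px >= 80 &
                    d3$manifest$trunk_width_px <= 120))
  expect_equal(generate_dataset(1, seed = 1)$manifest$scene_id, 1)
  expect_error(generate_dataset(5, list(trunk_width_px = c(100, 60))),
               class = "stemspot_parameter_error")
  expect_error(generate_dataset(0), class = "stemspot_parameter_error")
})

test_that("disturbing blobs stay near borders and clear of the spot", {
  ds <- generate_dataset(15, list(n_disturbing_blobs = c(3, 5)), seed = 21)
  for (sc in ds$scenes) {
    p <- sc$truth$params
    border <- max(4, round(0.10 * min(dim(sc$image))))
    for (b in sc$truth$blobs) {
      near_border <- b$centroid[1] <= border + 1 ||
        b$centroid[1] >= nrow(sc$image) - border - 1 ||
        b$centroid[2] <= border + 1 ||
        b$centroid[2] >= ncol(sc$image) - border - 1
      expect_true(near_border)
      expect_gt(sqrt(sum((b$centroid - p$spot_centroid)^2)),
                1.5 * p$spot_diameter_px / 2)
    }
  }
})

test_that("scene files round-trip through PNG/JSON", {
  dir <- withr::local_tempdir()
  sc <- clean_scene()
  paths <- write_scene(sc, dir, "t1")
  expect_true(all(file.exists(paths)))
  img <- read_gray_image(paths[["image"]])
  # 8-bit quantisation: half a gray level
  expect_lt(max(abs(img - sc$image)), 0.51)
  mask <- read_gray_image(paths[["mask"]])
  expect_setequal(unique(as.vector(mask)), c(0, 255))
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$trunk_width_px, sc$truth$trunk_width_px)
})
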