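# Spot detection: morphology, CSE extraction, cropping, selection,
# thresholding, edge geometry and the full pipeline.

test_that("opening is anti-extensive and removes sub-element blobs", {
  const <- matrix(100, 40, 40)
  expect_equal(sda_opening(const, 3), const)

  spike <- matrix(10, 40, 40)
  spike[20, 20] <- 250
  opened <- sda_opening(spike, 2)
  expect_equal(opened[20, 20], 10)

  set.seed(42)
  for (i in 1:12) {
    img <- matrix(runif(30 * 30, 0, 255), 30, 30)
    expect_true(all(sda_opening(img, 2) <= img + 1e-9))
  }
  expect_error(sda_opening(const, 25), class = "stemspot_parameter_error")
  expect_error(sda_opening(const, 0), class = "stemspot_parameter_error")
})

test_that("CSE extraction finds the spot cap and counts blobs", {
  expect_length(extract_cse(matrix(50, 30, 30), matrix(50, 30, 30))$components, 0)

  sc <- clean_scene()
  opened <- sda_opening(sc$image, 8)
  cse <- extract_cse(sc$image, opened)
  expect_length(cse$components, 1)
  diffimg <- pmax(sc$image - opened, 0)
  ref <- brute_weighted_centroid(diffimg, mean(diffimg) + 3 * sd(diffimg))
  expect_lt(sqrt(sum((cse$components[[1]]$centroid - ref)^2)), 1e-9)
  expect_lt(sqrt(sum((cse$components[[1]]$centroid - sc$truth$spot_centroid)^2)), 1)

  scb <- generate_scene(scene_params(
    noise_sigma = 0, illumination_gradient_amplitude = 0,
    n_disturbing_blobs = 3, blob_diameter_range_px = c(6, 9), seed = 4
  ))
  cseb <- extract_cse(scb$image, sda_opening(scb$image, 8))
  expect_length(cseb$components, 4)

  expect_error(extract_cse(matrix(0, 10, 10), matrix(0, 12, 12)),
               class = "stemspot_shape_error")
})

test_that("crop arithmetic matches the 15/16 contract", {
  img <- matrix(0, 1080, 1920)
  cs <- crop_step(img)
  expect_identical(dim(cs$image), c(1012L, 1800L))
  expect_equal(cs$offset, c(34, 60))

  # composition: two successive crops floor-compose and offsets add
  img2 <- matrix(seq_len(270 * 480) %% 251, 270, 480)
  c1 <- crop_step(img2)
  c2 <- crop_step(c1$image, c1$offset)
  expect_identical(nrow(c2$image), as.integer(floor(floor(270 * 15 / 16) * 15 / 16)))
  expect_identical(ncol(c2$image), as.integer(floor(floor(480 * 15 / 16) * 15 / 16)))
  # translation: content at original (r, c) appears at (r - off_r, c - off_c)
  r0 <- 150; c0 <- 300
  expect_equal(c2$image[r0 - c2$offset[1], c0 - c2$offset[2]], img2[r0, c0])
  expect_error(crop_step(matrix(0, 10, 40)), class = "stemspot_parameter_error")
})

test_that("spot component selection is the centre-distance argmin", {
  mk_cse <- function(centroids, areas, dim = c(100, 100)) {
    comps <- lapply(seq_len(nrow(centroids)), function(i) {
      list(centroid = centroids[i, ], area_px = areas[i], pixels = NULL)
    })
    structure(list(components = comps,
                   image_centroid = (dim + 1) / 2,
                   crop_offset = c(0, 0), dim = dim),
              class = "stemspot_cse")
  }
  one <- mk_cse(matrix(c(10, 10), 1), 5)
  expect_equal(select_spot_component(one)$centroid, c(10, 10))

  two <- mk_cse(rbind(c(50.5, 50.5), c(2, 2)), c(4, 400))
  expect_equal(select_spot_component(two)$centroid, c(50.5, 50.5))

  set.seed(9)
  for (rep in 1:5) {
    cents <- matrix(runif(20, 1, 100), 10, 2)
    areas <- sample(5:50, 10)
    cse <- mk_cse(cents, areas)
    got <- select_spot_component(cse)$centroid
    d <- sqrt(rowSums((cents - matrix(cse$image_centroid, 10, 2, byrow = TRUE))^2))
    expect_equal(got, cents[which.min(d), ])
  }
  expect_error(select_spot_component(mk_cse(matrix(0, 0, 2), numeric(0))),
               class = "stemspot_no_spot_error")
})

test_that("centroid correction is the exact crop translation", {
  expect_equal(correct_centroid(c(100, 200), c(0, 0)), c(100, 200))
  expect_equal(correct_centroid(c(100, 200), c(34, 60)), c(134, 260))

  # round-trip on a cropped scene: crop twice, detect, correct
  sc <- clean_scene(seed = 6)
  c1 <- crop_step(sc$image)
  c2 <- crop_step(c1$image, c1$offset)
  cse <- extract_cse(c2$image, sda_opening(c2$image, 8))
  comp <- select_spot_component(cse)
  corrected <- correct_centroid(comp$centroid, c2$offset)
  expect_lt(sqrt(sum((corrected - sc$truth$spot_centroid)^2)), 1)
})

test_that("intensity thresholding implements the mean-shifted half label", {
  img <- matrix(100, 50, 50) # mu = 100 exactly
  img[1, 1] <- 100 # keep mean
  gs <- gray_stats(img, eta = 255)
  expect_equal(gs$mu, 100)
  probe <- img
  probe[2, 2] <- 200; probe[3, 3] <- 240
  # stats computed on img (mu 100): threshold is 227.5
  out <- threshold_spot(probe, gs)
  expect_equal(out[2, 2], 0)
  expect_equal(out[3, 3], 255)

  zero <- matrix(0, 20, 20)
  expect_true(all(threshold_spot(zero, gray_stats(zero)) == 0))

  set.seed(3)
  ri <- matrix(runif(400, 0, 255), 20, 20)
  out2 <- threshold_spot(ri, gray_stats(ri, eta = 200))
  expect_true(all(out2 %in% c(0, 200)))
})

test_that("edge points land on the gradient ring", {
  # flat disk with a hard edge: selected points sit on the boundary ring
  h <- 101
  rows <- matrix(seq_len(h), h, h)
  cols <- t(rows)
  rho <- sqrt((rows - 51)^2 + (cols - 51)^2)
  disk <- matrix(0, h, h)
  disk[rho <= 20] <- 200
  region <- matrix(0, h, h); region[rho <= 20] <- 255
  pts <- select_edge_points(disk, region, c(51, 51))
  expect_gte(nrow(pts), 3)
  expect_true(all(abs(attr(pts, "radius") - 20) <= 1.5))

  # perfect rendered spot: points within 1.5 px of the nominal radius
  sc <- clean_scene(spot_diameter_px = 20)
  core <- threshold_spot(sc$image, gray_stats(sc$image))
  pts2 <- select_edge_points(sc$image, core, sc$truth$spot_centroid)
  expect_true(all(abs(attr(pts2, "radius") - 10) <= 1.5))

  # k grows monotonically as the acceptance fraction is relaxed
  ks <- vapply(c(0.9, 0.7, 0.5, 0.3, 0.1), function(q) {
    nrow(select_edge_points(sc$image, core, sc$truth$spot_centroid,
                            min_gradient_frac = q))
  }, numeric(1))
  expect_true(all(diff(ks) >= 0))

  expect_error(select_edge_points(disk, matrix(0, h, h), c(51, 51)),
               class = "stemspot_insufficient_edge_error")
})

test_that("circle fit reproduces exact and hand-computed cases", {
  th <- 2 * pi * (0:7) / 8
  pts <- cbind(50 + 50 * sin(th), 60 + 50 * cos(th))
  fit <- fit_circle(pts, c(50, 60))
  expect_equal(fit$diameter_px, 100, tolerance = 1e-9)
  expect_lt(fit$rms_residual, 1e-9)

  # mean radial distance, doubled: distances 9, 10, 11 give diameter 20
  pts3 <- rbind(c(0, 9), c(10, 0), c(-11, 0))
  fit3 <- fit_circle(pts3, c(0, 0), refine = FALSE)
  expect_equal(fit3$diameter_px, 2 / 3 * 30, tolerance = 1e-12)
  expect_equal(fit3$diameter_px_centroid, 20, tolerance = 1e-12)

  expect_error(fit_circle(pts3[1:2, ], c(0, 0)),
               class = "stemspot_insufficient_edge_error")
})

test_that("circle fit with refinement matches the grid-search oracle under noise", {
  set.seed(11)
  for (rep in 1:6) {
    r <- runif(1, 30, 50)
    ctr <- c(100, 120) + runif(2, -2, 2)
    th <- runif(200, 0, 2 * pi)
    rad <- r + rnorm(200, 0, 0.5)
    pts <- cbind(ctr[1] + rad * sin(th), ctr[2] + rad * cos(th))
    fit <- fit_circle(pts, c(100, 120))
    oracle <- circle_fit_grid_oracle(pts, c(100, 120))
    expect_lt(abs(fit$diameter_px - oracle$diameter_px), 0.5)
    expect_lt(abs(fit$diameter_px - 2 * r), 1)
  }
})

test_that("the full SDA recovers clean scenes and refuses blank ones", {
  sc <- clean_scene(spot_diameter_px = 18, seed = 12)
  fit <- run_sda(sc$image)
  expect_lt(sqrt(sum((fit$centroid - sc$truth$spot_centroid)^2)), 2)
  expect_lt(abs(fit$diameter_px - 18) / 18, 0.05)
  expect_gte(fit$k, 3)
  expect_gt(fit$diameter_px_centroid, 0)

  # blank trunk, no spot: a no-spot error, never a spurious fit
  set.seed(5)
  blank <- matrix(40, 270, 480)
  blank[, 180:300] <- 90
  blank <- stemspot:::clamp(blank + matrix(rnorm(270 * 480, 0, 1), 270, 480), 0, 255)
  expect_error(run_sda(blank), class = "stemspot_no_spot_error")
})

test_that("aggregate SDA error grows with sensor noise", {
  levels <- c(0, 1, 2, 3, 4)
  mean_err <- vapply(levels, function(ns) {
    errs <- vapply(1:10, function(s) {
      sc <- generate_scene(scene_params(noise_sigma = ns, spot_diameter_px = 14,
                                        n_disturbing_blobs = 0, seed = s))
      fit <- run_sda(sc$image)
      abs(fit$diameter_px - 14) / 14 +
        sqrt(sum((fit$centroid - sc$truth$spot_centroid)^2)) / 14
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_gt(mean_err[5], mean_err[1])
  expect_gt(cor(levels, mean_err), 0)
})
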