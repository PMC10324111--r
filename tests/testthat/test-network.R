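# Attention-augmented nested U-net: module contracts, gradients, loss
# weighting and smoke trainability.

test_that("local crops follow the m/n area rule and stay inside the frame", {
  x <- matrix(runif(480 * 270), 270, 480)
  full <- local_crop(x, c(100, 200), 6, 6)
  expect_identical(dim(full), dim(x))

  half <- local_crop(x, c(135, 240), 3, 6)
  target <- 0.5 * 270 * 480
  expect_lte(abs(prod(dim(half)) - target), sum(dim(half)))

  corner <- local_crop(x, c(1, 1), 2, 6)
  w <- attr(corner, "window")
  expect_true(w[1] >= 1 && w[3] >= 1 && w[2] <= 270 && w[4] <= 480)
  expect_equal(prod(dim(corner)), prod(dim(local_crop(x, c(135, 240), 2, 6))))
  expect_error(local_crop(x, c(1, 1), 7, 6), class = "stemspot_parameter_error")
})

test_that("attach preserves shape and reduces to the identity when zeroed", {
  set.seed(1)
  for (shape in list(c(8, 8, 2), c(12, 6, 4), c(5, 9, 1))) {
    w <- attach_init(shape[3], 3)
    x <- array(rnorm(prod(shape)), shape)
    xl <- matrix(runif(30), 6, 5)
    out <- attach_forward(x, xl, w)
    expect_identical(dim(out), as.integer(shape))

    w0 <- w
    w0[["conv4.W"]][] <- 0
    w0[["conv4.b"]][] <- 0
    expect_equal(attach_forward(x, xl, w0), x)
  }
})

test_that("gradients flow to all four attach convolutions", {
  set.seed(2)
  w <- attach_init(2, 3)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  xl <- matrix(runif(64), 8, 8)
  loss_of <- function(w) {
    tape <- stemspot:::tape_new()
    cache <- new.env(parent = emptyenv())
    xn <- stemspot:::t_const(tape, x)
    xln <- stemspot:::t_const(tape, stemspot:::as_hwc(xl))
    out <- stemspot:::attach_tape(tape, w, cache, "", xn, xln, 8L)
    sq <- stemspot:::node_new(tape, sum(out$value^2), parents = list(
      list(node = out, bw = function(g) g * 2 * out$value)))
    list(tape = tape, node = sq)
  }
  l <- loss_of(w)
  stemspot:::tape_backward(l$tape, l$node)
  gr <- stemspot:::tape_param_grads(l$tape)
  eps <- 1e-6
  for (nm in c("conv1.W", "conv2.W", "conv3.W", "conv4.W")) {
    expect_gt(max(abs(gr[[nm]])), 0)
    i <- which.max(abs(gr[[nm]]))
    wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
    wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
    num <- (loss_of(wp)$node$value - loss_of(wm)$node$value) / (2 * eps)
    expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
  }
})

test_that("A-RSU keeps spatial dims, reduces to F(x) when U and attach vanish", {
  set.seed(3)
  w <- c(attach_init(4, 3, "attach."), stemspot:::rsu_init(4, 3, 6, 2, "rsu."))
  x <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  xl <- matrix(runif(36), 6, 6)
  out <- arsu_forward(x, xl, w, rsu_depth = 2)
  expect_identical(dim(out)[1:2], dim(x)[1:2])

  # zero the attach projection and the final decoder conv: the residual
  # path leaves exactly F(x) = relu(conv_in(x))
  w0 <- w
  w0[["attach.conv4.W"]][] <- 0; w0[["attach.conv4.b"]][] <- 0
  w0[["rsu.d1.W"]][] <- 0; w0[["rsu.d1.b"]][] <- 0
  got <- arsu_forward(x, xl, w0, rsu_depth = 2)
  fx <- stemspot:::conv2d_raw(x, w[["rsu.conv_in.W"]], w[["rsu.conv_in.b"]])$y
  expect_equal(got, pmax(fx, 0), tolerance = 1e-12)

  # the A-RSU strictly extends the plain RSU parameter set
  expect_gt(length(w), length(stemspot:::rsu_init(4, 3, 6, 2)))
})

test_that("phi weights follow the coverage rule", {
  expect_equal(compute_phi(6, 6), 1)
  expect_equal(compute_phi(3, 6), 0.5)
  expect_equal(compute_phi(1, 6), 5 / 6)
  expect_equal(vapply(1:6, compute_phi, numeric(1), n = 6),
               c(1 - (1:5) / 6, 1))
  expect_equal(compute_phi(3, 6, reading = "linear"), 1 - sqrt(0.5))
  expect_equal(compute_phi(2, 6, local_resolution = c(10, 10),
                           full_resolution = c(10, 10)), 1)
  expect_equal(compute_phi(2, 6, local_resolution = c(5, 10),
                           full_resolution = c(10, 10)), 0.5)
})

test_that("training loss is a weighted BCE sum with exact phi scaling", {
  set.seed(4)
  truth <- matrix(sample(c(0, 255), 64, TRUE), 8, 8)
  sides <- lapply(1:6, function(i) matrix(runif(64, 0.05, 0.95), 8, 8))
  fused <- matrix(runif(64, 0.05, 0.95), 8, 8)

  lc <- loss_config(6)
  l <- training_loss(sides, fused, truth, lc)
  expect_gte(l, 0)

  # perfect prediction: loss ~ 0
  perfect <- lapply(1:6, function(i) truth / 255)
  expect_lt(training_loss(perfect, truth / 255, truth, lc), 1e-5)

  # all omega zero: loss 0
  lc0 <- loss_config(6, omega_side = 0, omega_fuse = 0)
  expect_equal(training_loss(sides, fused, truth, lc0), 0)

  # halving phi for one stage removes exactly half that side contribution
  lc_half <- lc
  lc_half$phi[2] <- lc$phi[2] / 2
  bce <- function(p, t) -mean(t * log(p + 1e-7) + (1 - t) * log(1 - p + 1e-7))
  delta <- training_loss(sides, fused, truth, lc) -
    training_loss(sides, fused, truth, lc_half)
  expect_equal(delta, 0.5 * lc$phi[2] * bce(sides[[2]], truth / 255),
               tolerance = 1e-12)

  bad <- sides; bad[[1]][1, 1] <- NaN
  expect_error(training_loss(bad, fused, truth), class = "stemspot_numeric_error")
})

test_that("forward maps live in [0,1], match input dims, and are deterministic", {
  cfg <- net_config()
  net <- list(weights = net_init(cfg, seed = 11), config = cfg)
  sc <- clean_scene()
  o1 <- net_forward(net, sc$image, sc$truth$spot_centroid)
  expect_identical(dim(o1$fused), dim(sc$image))
  expect_length(o1$sides, 6)
  for (s in o1$sides) {
    expect_identical(dim(s), dim(sc$image))
    expect_true(all(s >= 0 & s <= 1))
  }
  expect_true(all(o1$fused >= 0 & o1$fused <= 1))
  o2 <- net_forward(net, sc$image, sc$truth$spot_centroid)
  expect_identical(o1, o2)
  expect_message(net_forward(net, sc$image), "image centre")
})

test_that("toy training is deterministic under the seed and records a curve", {
  ds <- generate_dataset(4, seed = 13)
  cfg <- net_config(input_size = 16L, base_channels = 4L, mid_channels = 2L)
  n1 <- train_toy(ds$scenes, config = cfg, n_iterations = 4, seed = 13)
  n2 <- train_toy(ds$scenes, config = cfg, n_iterations = 4, seed = 13)
  expect_identical(n1$loss_curve, n2$loss_curve)
  expect_identical(n1$weights, n2$weights)
  expect_length(n1$loss_curve, 4)
  expect_true(all(is.finite(n1$loss_curve)))
  expect_error(train_toy(ds$scenes[1:3], config = cfg),
               class = "stemspot_parameter_error")
})

test_that("checkpoints round-trip", {
  ds <- generate_dataset(4, seed = 14)
  cfg <- net_config(input_size = 16L, base_channels = 4L, mid_channels = 2L)
  net <- train_toy(ds$scenes, config = cfg, n_iterations = 2, seed = 14)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(net, path)
  back <- load_checkpoint(path)
  expect_equal(back$weights, net$weights)
  o1 <- net_forward(net, ds$scenes[[1]]$image, ds$scenes[[1]]$truth$spot_centroid)
  o2 <- net_forward(back, ds$scenes[[1]]$image, ds$scenes[[1]]$truth$spot_centroid)
  expect_identical(o1, o2)
})
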