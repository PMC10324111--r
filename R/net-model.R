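# Attention-augmented nested U-net for trunk saliency.
#
# The network is a two-level nested U-structure: six encoder stages and five
# decoder stages, each a ReSidual U-block (RSU) computing U(F(x)) + F(x)
# where F is a weight layer and U a small symmetric encoder-decoder.
# Encoder stages are augmented into A-RSU blocks by an Attach attention
# module that injects a spot-centred local crop of the input image: the
# m-th stage sees a crop whose area is m/n of the frame (n = 6 stages), so
# early stages attend tightly around the laser spot and the last stage sees
# the whole frame. Six side saliency maps plus a fused map are deeply
# supervised with binary cross-entropy; side losses are scaled by the
# coverage weight phi_m = 1 - m/n (1 for m = n).
#
# The implementation targets CPU-scale smoke training on synthetic scenes:
# small channel counts, no normalization layers, full-batch Adam.

#' Network configuration
#'
#' @param input_size Square network input size in pixels (resized in/out);
#'   must be divisible by 8.
#' @param n_stages Number of encoder stages (the nested-U design uses 6).
#' @param base_channels Stage output channels.
#' @param mid_channels RSU internal channels.
#' @param attach_channels Embedding channels of the Attach module.
#' @param attn_size Attention grid cap: affinity matrices are computed on
#'   feature maps pooled to at most this size per side.
#' @param rsu_depth Encoder-decoder depth inside each RSU.
#' @param phi_reading `"area"` (phi_m = 1 - m/n) or `"linear"`
#'   (phi_m = 1 - sqrt(m/n)) reading of the local-map resolution ratio.
#' @return List of class `stemspot_net_config`, including the per-stage
#'   resolution schedule.
#' @export
net_config <- function(input_size = 32L, n_stages = 6L, base_channels = 6L,
                       mid_channels = 3L, attach_channels = 3L,
                       attn_size = 8L, rsu_depth = 2L,
                       phi_reading = c("area", "linear")) {
  if (input_size %% 8 != 0) stop_parameter("input_size must be divisible by 8")
  if (n_stages < 2) stop_parameter("n_stages must be at least 2")
  res <- integer(n_stages)
  res[1] <- input_size
  for (m in 2:n_stages) {
    res[m] <- if (res[m - 1] >= 8 && m <= 4) res[m - 1] %/% 2L else res[m - 1]
  }
  structure(list(
    input_size = as.integer(input_size), n_stages = as.integer(n_stages),
    base_channels = as.integer(base_channels),
    mid_channels = as.integer(mid_channels),
    attach_channels = as.integer(attach_channels),
    attn_size = as.integer(attn_size), rsu_depth = as.integer(rsu_depth),
    phi_reading = match.arg(phi_reading),
    stage_resolution = res
  ), class = "stemspot_net_config")
}

he_init <- function(kh, kw, ci, co, scale = 1) {
  array(rnorm(kh * kw * ci * co, 0, scale * sqrt(2 / (kh * kw * ci))),
        c(kh, kw, ci, co))
}

attach_param_names <- function(prefix = "") {
  paste0(prefix, c("conv1.W", "conv1.b", "conv2.W", "conv2.b",
                   "conv3.W", "conv3.b", "conv4.W", "conv4.b"))
}

#' Initialise Attach module weights
#'
#' @param c_x Channels of the input feature map x.
#' @param c_a Embedding channels.
#' @param prefix Name prefix for the flat weight list.
#' @return Named list of arrays (`conv1..conv4`, weights and biases).
#'   `conv4` (the output projection) is initialised near zero so the module
#'   starts close to the identity.
#' @export
attach_init <- function(c_x, c_a, prefix = "") {
  w <- list()
  w[[paste0(prefix, "conv1.W")]] <- he_init(1, 1, c_x, c_a)
  w[[paste0(prefix, "conv1.b")]] <- numeric(c_a)
  w[[paste0(prefix, "conv2.W")]] <- he_init(1, 1, 1, c_a)
  w[[paste0(prefix, "conv2.b")]] <- numeric(c_a)
  w[[paste0(prefix, "conv3.W")]] <- he_init(1, 1, 1, c_a)
  w[[paste0(prefix, "conv3.b")]] <- numeric(c_a)
  w[[paste0(prefix, "conv4.W")]] <- he_init(1, 1, c_a, c_x, scale = 0.01)
  w[[paste0(prefix, "conv4.b")]] <- numeric(c_x)
  w
}

rsu_init <- function(c_in, c_mid, c_out, depth, prefix = "") {
  w <- list()
  add <- function(nm, kh, kw, ci, co) {
    w[[paste0(prefix, nm, ".W")]] <<- he_init(kh, kw, ci, co)
    w[[paste0(prefix, nm, ".b")]] <<- numeric(co)
  }
  add("conv_in", 3, 3, c_in, c_out)
  add("e1", 3, 3, c_out, c_mid)
  if (depth >= 2) for (l in 2:depth) add(paste0("e", l), 3, 3, c_mid, c_mid)
  add("bottom", 3, 3, c_mid, c_mid)
  if (depth >= 2) for (l in depth:2) add(paste0("d", l), 3, 3, 2 * c_mid, c_mid)
  add("d1", 3, 3, 2 * c_mid, c_out)
  w
}

#' Initialise all network weights
#'
#' @param config A [net_config()] object.
#' @param seed Integer seed for the weight draw.
#' @return Flat named list of arrays (class `stemspot_net_weights`).
#' @export
net_init <- function(config = net_config(), seed = 1L) {
  set.seed(seed)
  cfg <- config
  co <- cfg$base_channels; cm <- cfg$mid_channels
  n <- cfg$n_stages
  w <- list()
  for (m in seq_len(n)) {
    c_in <- if (m == 1) 1L else co
    w <- c(w, attach_init(c_in, cfg$attach_channels, paste0("en", m, ".attach.")))
    w <- c(w, rsu_init(c_in, cm, co, cfg$rsu_depth, paste0("en", m, ".rsu.")))
  }
  for (m in seq_len(n - 1)) {
    w <- c(w, rsu_init(2L * co, cm, co, cfg$rsu_depth, paste0("de", m, ".rsu.")))
  }
  for (m in seq_len(n)) {
    w[[paste0("side", m, ".W")]] <- he_init(3, 3, co, 1)
    w[[paste0("side", m, ".b")]] <- numeric(1)
  }
  w[["fuse.W"]] <- he_init(1, 1, n, 1)
  w[["fuse.b"]] <- numeric(1)
  class(w) <- "stemspot_net_weights"
  w
}

#' Spot-centred local crop of a map
#'
#' Returns the axis-aligned window centred on the spot centroid (clamped so
#' the window lies fully inside the frame) whose area is `m / n` of the
#' input map's area, at the input's aspect ratio. For `m = n` the whole map
#' is returned.
#'
#' @param x Matrix or `(H, W, C)` array.
#' @param spot_centroid `(row, col)` centre, in `x` coordinates.
#' @param m Stage index, `1 <= m <= n`.
#' @param n Stage count.
#' @return The cropped map (same type as `x`), with the window
#'   `(r0, r1, c0, c1)` in attribute `"window"`.
#' @export
local_crop <- function(x, spot_centroid, m, n) {
  if (!is_count(m) || m < 1 || m > n) stop_parameter("m must satisfy 1 <= m <= n")
  arr <- is.array(x) && length(dim(x)) == 3
  h <- dim(x)[1]; w <- dim(x)[2]
  if (m == n) {
    out <- x
    attr(out, "window") <- c(1, h, 1, w)
    return(out)
  }
  s <- sqrt(m / n)
  hh <- max(1L, round(h * s)); ww <- max(1L, round(w * s))
  r0 <- round(spot_centroid[1] - hh / 2)
  c0 <- round(spot_centroid[2] - ww / 2)
  r0 <- clamp(r0, 1, h - hh + 1)
  c0 <- clamp(c0, 1, w - ww + 1)
  out <- if (arr) x[r0:(r0 + hh - 1), c0:(c0 + ww - 1), , drop = FALSE]
         else x[r0:(r0 + hh - 1), c0:(c0 + ww - 1), drop = FALSE]
  attr(out, "window") <- c(r0, r0 + hh - 1, c0, c0 + ww - 1)
  out
}

#' Stage loss weight from local-map coverage
#'
#' `phi_m = 1 - R(x'_m) / R(x)` when the local map is a strict sub-window
#' and 1 when local and full maps coincide (`m = n`). Under the area
#' reading of the resolution ratio with the m/n-area crops this gives
#' `phi_m = 1 - m/n` for `m < n`; the linear-dimension reading gives
#' `1 - sqrt(m/n)`.
#'
#' @param m Stage index; @param n stage count.
#' @param local_resolution,full_resolution Optional explicit `(H, W)` pairs;
#'   when omitted the m/n-area crop relation is used.
#' @param reading `"area"` or `"linear"`.
#' @return The scalar weight.
#' @export
compute_phi <- function(m, n, local_resolution = NULL, full_resolution = NULL,
                        reading = c("area", "linear")) {
  reading <- match.arg(reading)
  if (!is_count(m) || m < 1 || m > n) stop_parameter("m must satisfy 1 <= m <= n")
  if (!is.null(local_resolution) && !is.null(full_resolution)) {
    if (all(local_resolution == full_resolution)) return(1)
    ratio <- prod(local_resolution) / prod(full_resolution)
  } else {
    if (m == n) return(1)
    ratio <- m / n
  }
  if (reading == "area") 1 - ratio else 1 - sqrt(ratio)
}

# ---- tape-level building blocks -------------------------------------------

get_param <- function(tape, w, cache, name) {
  if (is.null(cache[[name]])) cache[[name]] <- t_param(tape, w[[name]], name)
  cache[[name]]
}

conv_block <- function(tape, w, cache, prefix, x, dilation = 1L, relu = TRUE) {
  y <- t_conv2d(tape, x,
                get_param(tape, w, cache, paste0(prefix, ".W")),
                get_param(tape, w, cache, paste0(prefix, ".b")),
                dilation = dilation)
  if (relu) t_relu(tape, y) else y
}

# Attach: queries from the (pooled) input map, keys/values from the (pooled)
# local crop; row-softmax affinity; conv4 projects back to x's channels and
# the result is upsampled and added to x. Zeroed conv4 => exact identity.
attach_tape <- function(tape, w, cache, prefix, x, xl, attn_size) {
  h <- dim(x$value)[1]; wd <- dim(x$value)[2]
  ha <- min(h, attn_size); wa <- min(wd, attn_size)
  xp <- t_resize(tape, x, ha, wa)
  xlp <- t_resize(tape, xl, ha, wa)
  q <- conv_block(tape, w, cache, paste0(prefix, "conv1"), xp, relu = FALSE)
  k <- conv_block(tape, w, cache, paste0(prefix, "conv2"), xlp, relu = FALSE)
  v <- conv_block(tape, w, cache, paste0(prefix, "conv3"), xlp, relu = FALSE)
  ca <- dim(q$value)[3]
  qm <- t_reshape(tape, q, c(ha * wa, ca))
  km <- t_reshape(tape, k, c(ha * wa, ca))
  vm <- t_reshape(tape, v, c(ha * wa, ca))
  aff <- t_softmax_rows(tape, t_matmul(tape, qm, t_transpose(tape, km)))
  y <- t_matmul(tape, aff, vm)
  y <- t_reshape(tape, y, c(ha, wa, ca))
  y <- conv_block(tape, w, cache, paste0(prefix, "conv4"), y, relu = FALSE)
  y <- t_resize(tape, y, h, wd)
  t_add(tape, x, y)
}

# RSU: conv_in gives F(x); a small symmetric encoder-decoder U over it; the
# block returns U(F(x)) + F(x). `dilated` stages swap pooling/upsampling for
# growing dilation (resolution preserved).
rsu_tape <- function(tape, w, cache, prefix, x, depth, dilated = FALSE) {
  hin <- conv_block(tape, w, cache, paste0(prefix, "conv_in"), x)
  enc <- vector("list", depth)
  cur <- hin
  for (l in seq_len(depth)) {
    dil <- if (dilated) 2L^(l - 1L) else 1L
    if (!dilated && l > 1) cur <- t_maxpool2(tape, cur)
    cur <- conv_block(tape, w, cache, paste0(prefix, "e", l), cur, dilation = dil)
    enc[[l]] <- cur
  }
  bdil <- if (dilated) 2L^depth else 2L
  d <- conv_block(tape, w, cache, paste0(prefix, "bottom"), enc[[depth]],
                  dilation = bdil)
  for (l in rev(seq_len(depth))) {
    dil <- if (dilated) 2L^(l - 1L) else 1L
    d <- conv_block(tape, w, cache, paste0(prefix, "d", l),
                    t_concat(tape, d, enc[[l]]), dilation = dil)
    if (!dilated && l > 1) {
      tgt <- dim(enc[[l - 1]]$value)
      d <- t_resize(tape, d, tgt[1], tgt[2])
    }
  }
  t_add(tape, d, hin)
}

# Full forward pass on the tape. `img_small`: input_size x input_size matrix
# in [0, 1]; `centroid_small`: spot centroid in input coordinates;
# `truth_small`: optional 0/1 matrix to also build the training loss.
net_forward_tape <- function(tape, w, cfg, img_small, centroid_small,
                             truth_small = NULL, lcfg = NULL) {
  cache <- new.env(parent = emptyenv())
  n <- cfg$n_stages
  res <- cfg$stage_resolution
  x <- t_const(tape, as_hwc(img_small))
  skips <- vector("list", n)
  for (m in seq_len(n)) {
    crop <- local_crop(img_small, centroid_small, m, n)
    xl <- t_const(tape, as_hwc(resize_gray(unclass_window(crop), res[m], res[m])))
    x1 <- attach_tape(tape, w, cache, paste0("en", m, ".attach."), x, xl,
                      cfg$attn_size)
    x <- rsu_tape(tape, w, cache, paste0("en", m, ".rsu."), x1,
                  cfg$rsu_depth, dilated = res[m] <= 8)
    skips[[m]] <- x
    if (m < n && res[m + 1] < res[m]) x <- t_maxpool2(tape, x)
  }
  d <- skips[[n]]
  dec <- vector("list", n - 1)
  for (m in rev(seq_len(n - 1))) {
    if (res[m] > dim(d$value)[1]) d <- t_resize(tape, d, res[m], res[m])
    d <- rsu_tape(tape, w, cache, paste0("de", m, ".rsu."),
                  t_concat(tape, d, skips[[m]]),
                  cfg$rsu_depth, dilated = res[m] <= 8)
    dec[[m]] <- d
  }
  logits <- vector("list", n)
  for (m in seq_len(n)) {
    src <- if (m == n) skips[[n]] else dec[[m]]
    lg <- conv_block(tape, w, cache, paste0("side", m), src, relu = FALSE)
    logits[[m]] <- t_resize(tape, lg, cfg$input_size, cfg$input_size)
  }
  alll <- logits[[1]]
  for (m in 2:n) alll <- t_concat(tape, alll, logits[[m]])
  fuse_logit <- conv_block(tape, w, cache, "fuse", alll, relu = FALSE)
  sides <- lapply(logits, function(l) t_sigmoid(tape, l))
  fused <- t_sigmoid(tape, fuse_logit)

  loss <- NULL
  if (!is.null(truth_small)) {
    if (is.null(lcfg)) lcfg <- loss_config(n)
    tgt <- as_hwc(truth_small)
    terms <- list(); wts <- numeric(0)
    for (m in seq_len(n)) {
      terms <- c(terms, list(t_bce_mean(tape, sides[[m]], tgt)))
      wts <- c(wts, lcfg$omega_side[m] * lcfg$phi[m])
      terms <- c(terms, list(t_bce_mean(tape, fused, tgt)))
      wts <- c(wts, lcfg$omega_fuse[m])
    }
    loss <- t_weighted_sum(tape, terms, wts)
  }
  list(fused = fused, sides = sides, loss = loss)
}

unclass_window <- function(x) {
  attr(x, "window") <- NULL
  x
}

#' Deep-supervision loss configuration
#'
#' @param n_stages Number of side maps.
#' @param omega_side,omega_fuse Per-stage weights of the side and fused
#'   cross-entropy terms (recycled to length `n_stages`); defaults 1.
#' @param phi Per-stage coverage weights; default `compute_phi(m, n)` for
#'   each stage (1 - m/n, and 1 at m = n).
#' @param reading Passed to [compute_phi()] when `phi` is derived.
#' @return List of class `stemspot_loss_config`.
#' @export
loss_config <- function(n_stages = 6L, omega_side = 1, omega_fuse = 1,
                        phi = NULL, reading = "area") {
  if (is.null(phi)) {
    phi <- vapply(seq_len(n_stages), compute_phi, numeric(1), n = n_stages,
                  reading = reading)
  }
  if (any(omega_side < 0) || any(omega_fuse < 0)) {
    stop_parameter("loss weights must be non-negative")
  }
  if (abs(phi[n_stages] - 1) > 1e-12) {
    stop_parameter("phi must equal 1 at the last stage")
  }
  structure(list(omega_side = rep_len(omega_side, n_stages),
                 omega_fuse = rep_len(omega_fuse, n_stages),
                 phi = phi, n_stages = n_stages),
            class = "stemspot_loss_config")
}

bce_mean <- function(p, t, eps = 1e-7) {
  -mean(t * log(p + eps) + (1 - t) * log(1 - p + eps))
}

#' Deep-supervision training loss on plain maps
#'
#' `L = sum_m omega_side_m * l_side_m * phi_m + omega_fuse_m * l_fuse`, with
#' `l` the mean pixelwise binary cross-entropy of each saliency map against
#' the truth mask.
#'
#' @param side_maps List of saliency matrices in \[0, 1\].
#' @param fused_map Fused saliency matrix.
#' @param truth_mask Matrix over \{0, 255\} (or \{0, 1\}).
#' @param lcfg A [loss_config()] object.
#' @return Non-negative scalar.
#' @export
training_loss <- function(side_maps, fused_map, truth_mask,
                          lcfg = loss_config(length(side_maps))) {
  maps <- c(side_maps, list(fused_map))
  for (mp in maps) {
    if (!identical(dim(mp), dim(truth_mask))) {
      stop_shape("all maps and the truth mask must share dimensions")
    }
    if (anyNA(mp) || any(!is.finite(mp))) stop_numeric("NaN in saliency maps")
  }
  tgt <- if (max(truth_mask) > 1) truth_mask / 255 else truth_mask
  n <- length(side_maps)
  l_fuse <- bce_mean(fused_map, tgt)
  total <- 0
  for (m in seq_len(n)) {
    total <- total + lcfg$omega_side[m] * bce_mean(side_maps[[m]], tgt) * lcfg$phi[m] +
      lcfg$omega_fuse[m] * l_fuse
  }
  total
}

# ---- user-facing forward / training ---------------------------------------

prepare_net_input <- function(img, spot_centroid, cfg) {
  assert_gray_image(img)
  if (is.null(spot_centroid)) {
    message("no spot centroid supplied; falling back to the image centre")
    spot_centroid <- (dim(img) + 1) / 2
  }
  s <- cfg$input_size
  list(img_small = resize_gray(img, s, s) / 255,
       centroid_small = c(spot_centroid[1] * s / nrow(img),
                          spot_centroid[2] * s / ncol(img)))
}

#' Forward pass of the trunk saliency network
#'
#' Resizes the image to the network input size, runs the six-stage nested
#' encoder-decoder with spot-conditioned local crops, and returns the fused
#' and side saliency maps upsampled back to the input dimensions.
#'
#' @param net A trained network from [train_toy()], or a list with elements
#'   `weights` and `config`.
#' @param img Gray image matrix (0-255).
#' @param spot_centroid `(row, col)` of the laser spot; `NULL` falls back to
#'   the image centre (with a message).
#' @return List with `fused` (matrix in \[0, 1\], same size as `img`) and
#'   `sides` (list of side maps).
#' @export
net_forward <- function(net, img, spot_centroid = NULL) {
  cfg <- net$config
  w <- net$weights
  inp <- prepare_net_input(img, spot_centroid, cfg)
  tape <- tape_new()
  out <- net_forward_tape(tape, w, cfg, inp$img_small, inp$centroid_small)
  h <- nrow(img); wd <- ncol(img)
  list(
    fused = clamp(resize_gray(out$fused$value[, , 1], h, wd), 0, 1),
    sides = lapply(out$sides, function(s) clamp(resize_gray(s$value[, , 1], h, wd), 0, 1))
  )
}

#' Standalone Attach module forward
#'
#' @param x Input feature map, matrix or `(H, W, C)` array.
#' @param x_local Local (spot-centred) map, matrix or array with one channel.
#' @param weights Flat weight list from [attach_init()] (prefix `""`).
#' @param attn_size Attention grid cap.
#' @return Array with exactly the shape of `x`.
#' @export
attach_forward <- function(x, x_local, weights, attn_size = 8L) {
  tape <- tape_new()
  cache <- new.env(parent = emptyenv())
  xn <- t_const(tape, as_hwc(x))
  xl <- t_const(tape, as_hwc(x_local))
  out <- attach_tape(tape, weights, cache, "", xn, xl, attn_size)
  out$value
}

#' Standalone A-RSU block forward
#'
#' Computes `U(F(x1)) + F(x1)` with `x1 = attach(x, x_local)`.
#'
#' @param x Input feature map, matrix or `(H, W, C)` array (spatial dims
#'   divisible by `2^rsu_depth` unless `dilated`).
#' @param x_local Local map (one channel).
#' @param weights Flat list containing `attach.*` ([attach_init()] with
#'   prefix `"attach."`) and `rsu.*` entries.
#' @param rsu_depth Inner U depth.
#' @param dilated Use dilation instead of pooling (resolution preserved).
#' @param attn_size Attention grid cap.
#' @return Feature map array with `x`'s spatial dimensions.
#' @export
arsu_forward <- function(x, x_local, weights, rsu_depth = 2L,
                         dilated = FALSE, attn_size = 8L) {
  tape <- tape_new()
  cache <- new.env(parent = emptyenv())
  xn <- t_const(tape, as_hwc(x))
  xl <- t_const(tape, as_hwc(x_local))
  x1 <- attach_tape(tape, weights, cache, "attach.", xn, xl, attn_size)
  out <- rsu_tape(tape, weights, cache, "rsu.", x1, rsu_depth, dilated = dilated)
  out$value
}

#' Train the network on synthetic scenes (smoke scale)
#'
#' Full-batch Adam (initial learning rate 1e-3, betas (0.9, 0.999),
#' eps 1e-8, weight decay 0) on a small set of synthetic scenes, recording
#' the loss at every iteration. Deterministic under `seed`.
#'
#' @param scenes List of at least 4 [generate_scene()] objects.
#' @param config A [net_config()].
#' @param lcfg A [loss_config()]; defaults to the config's stage count.
#' @param n_iterations Number of Adam steps.
#' @param lr,betas,eps,weight_decay Adam hyper-parameters.
#' @param seed Seed for weight initialisation.
#' @param verbose Print the loss every 10 iterations?
#' @return List of class `stemspot_net` with `weights`, `config`,
#'   `loss_config` and `loss_curve` (one entry per iteration).
#' @export
train_toy <- function(scenes, config = net_config(), lcfg = NULL,
                      n_iterations = 50L, lr = 1e-3, betas = c(0.9, 0.999),
                      eps = 1e-8, weight_decay = 0, seed = 1L,
                      verbose = FALSE) {
  if (length(scenes) < 4) stop_parameter("training needs at least 4 scenes")
  cfg <- config
  if (is.null(lcfg)) lcfg <- loss_config(cfg$n_stages)
  w <- net_init(cfg, seed = seed)

  inputs <- lapply(scenes, function(sc) {
    s <- cfg$input_size
    list(
      img_small = resize_gray(sc$image, s, s) / 255,
      centroid_small = c(sc$truth$spot_centroid[1] * s / nrow(sc$image),
                         sc$truth$spot_centroid[2] * s / ncol(sc$image)),
      truth_small = (resize_gray(sc$trunk_mask / 255, s, s) > 0.5) * 1
    )
  })

  nms <- names(w)
  m1 <- lapply(w, function(p) array(0, dim(p) %||% length(p)))
  v1 <- lapply(w, function(p) array(0, dim(p) %||% length(p)))
  curve <- numeric(n_iterations)

  for (it in seq_len(n_iterations)) {
    total <- 0
    grads <- NULL
    for (inp in inputs) {
      tape <- tape_new()
      out <- net_forward_tape(tape, w, cfg, inp$img_small, inp$centroid_small,
                              truth_small = inp$truth_small, lcfg = lcfg)
      total <- total + out$loss$value
      tape_backward(tape, out$loss)
      g <- tape_param_grads(tape)
      if (is.null(grads)) grads <- g
      else for (nm in nms) grads[[nm]] <- grads[[nm]] + g[[nm]]
    }
    total <- total / length(inputs)
    if (!is.finite(total)) {
      stop_training(sprintf("training diverged (non-finite loss) at iteration %d", it))
    }
    curve[it] <- total
    if (verbose && it %% 10 == 0) message(sprintf("iter %3d loss %.5f", it, total))
    for (nm in nms) {
      g <- grads[[nm]] / length(inputs)
      if (weight_decay > 0) g <- g + weight_decay * w[[nm]]
      m1[[nm]] <- betas[1] * m1[[nm]] + (1 - betas[1]) * g
      v1[[nm]] <- betas[2] * v1[[nm]] + (1 - betas[2]) * g^2
      mhat <- m1[[nm]] / (1 - betas[1]^it)
      vhat <- v1[[nm]] / (1 - betas[2]^it)
      w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  structure(list(weights = w, config = cfg, loss_config = lcfg,
                 loss_curve = curve),
            class = "stemspot_net")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a network checkpoint
#'
#' The checkpoint is a single RDS file holding weights, configuration and
#' the training loss curve.
#'
#' @param net A `stemspot_net` object.
#' @param path Destination file.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the `stemspot_net`.
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(unclass(net), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  structure(readRDS(path), class = "stemspot_net")
}
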