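# Synthetic panchromatic scene generator.
#
# Scenes emulate what the measurement device sees: a vertical trunk band over
# a darker background, smooth uneven illumination, a bright laser spot whose
# intensity falls off radially from the centroid, small bright disturbing
# blobs near the image borders, and additive sensor noise. Every scene comes
# with an exact trunk mask and a record of all true parameters, so each
# downstream stage can be tested against ground truth.

#' Scene parameters for the synthetic generator
#'
#' Builds and validates the full parameter set describing one synthetic
#' scene. Defaults describe a 480 x 270 frame (quarter scale of the device's
#' 1920 x 1080 sensor) with the laser spot near the frame centre, where the
#' coaxial laser of the device places it.
#'
#' @param image_height_px,image_width_px Frame size in pixels.
#' @param trunk_width_px Width of the vertical trunk band, pixels.
#' @param trunk_center_col_px Column of the trunk band centre.
#' @param trunk_intensity,background_intensity Gray levels (0-255) of trunk
#'   band and background.
#' @param illumination_gradient_amplitude Peak absolute value (gray levels)
#'   of the smooth additive shading surface emulating uneven lighting.
#' @param spot_centroid Numeric `(row, col)` of the laser spot centre; may be
#'   fractional.
#' @param spot_diameter_px True spot diameter in pixels (>= 3).
#' @param spot_peak_intensity Gray level at the spot centroid.
#' @param spot_edge_intensity Gray level at radius `spot_diameter_px / 2`;
#'   must be below the peak and at least the trunk intensity.
#' @param n_disturbing_blobs Number of small bright blobs placed near the
#'   image borders, outside the spot's bounding box.
#' @param blob_diameter_range_px Length-2 range of blob diameters, pixels.
#' @param noise_sigma Standard deviation of additive Gaussian sensor noise.
#' @param seed Integer seed; identical `(params, seed)` give a bit-identical
#'   scene.
#' @return A validated list of class `stemspot_scene_params`.
#' @seealso [generate_scene()], [generate_dataset()]
#' @export
scene_params <- function(image_height_px = 270L,
                         image_width_px = 480L,
                         trunk_width_px = 120L,
                         trunk_center_col_px = 240L,
                         trunk_intensity = 90,
                         background_intensity = 40,
                         illumination_gradient_amplitude = 25,
                         spot_centroid = c(135, 240),
                         spot_diameter_px = 16,
                         spot_peak_intensity = 255,
                         spot_edge_intensity = 140,
                         n_disturbing_blobs = 3L,
                         blob_diameter_range_px = c(3, 9),
                         noise_sigma = 2,
                         seed = 1L) {
  p <- list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    trunk_width_px = as.integer(trunk_width_px),
    trunk_center_col_px = as.integer(trunk_center_col_px),
    trunk_intensity = trunk_intensity,
    background_intensity = background_intensity,
    illumination_gradient_amplitude = illumination_gradient_amplitude,
    spot_centroid = as.numeric(spot_centroid),
    spot_diameter_px = as.numeric(spot_diameter_px),
    spot_peak_intensity = spot_peak_intensity,
    spot_edge_intensity = spot_edge_intensity,
    n_disturbing_blobs = as.integer(n_disturbing_blobs),
    blob_diameter_range_px = as.numeric(blob_diameter_range_px),
    noise_sigma = noise_sigma,
    seed = as.integer(seed)
  )
  class(p) <- "stemspot_scene_params"
  validate_scene_params(p)
  p
}

validate_scene_params <- function(p) {
  with(p, {
    if (image_height_px < 32 || image_width_px < 32) {
      stop_parameter("image dimensions must be at least 32 px")
    }
    if (trunk_width_px < 1) stop_parameter("trunk_width_px must be positive")
    for (nm in c("trunk_intensity", "background_intensity",
                 "spot_peak_intensity", "spot_edge_intensity")) {
      v <- p[[nm]]
      if (v < 0 || v > 255) stop_parameter(sprintf("%s must lie in [0, 255]", nm))
    }
    if (illumination_gradient_amplitude < 0 || illumination_gradient_amplitude > 255) {
      stop_parameter("illumination_gradient_amplitude must lie in [0, 255]")
    }
    if (spot_diameter_px < 3) stop_parameter("spot_diameter_px must be >= 3")
    if (!(spot_peak_intensity > spot_edge_intensity)) {
      stop_parameter("spot_peak_intensity must exceed spot_edge_intensity")
    }
    if (spot_edge_intensity < trunk_intensity) {
      stop_parameter("spot_edge_intensity must be >= trunk_intensity (spot locally brightest)")
    }
    # spot entirely inside the trunk band
    if (abs(spot_centroid[2] - trunk_center_col_px) + spot_diameter_px / 2 >
          trunk_width_px / 2) {
      stop_parameter("spot must lie entirely inside the trunk band: |spot_col - trunk_center| + d/2 <= width/2")
    }
    if (n_disturbing_blobs < 0) stop_parameter("n_disturbing_blobs must be non-negative")
    if (length(blob_diameter_range_px) != 2 ||
          blob_diameter_range_px[1] > blob_diameter_range_px[2] ||
          blob_diameter_range_px[1] < 3) {
      stop_parameter("blob_diameter_range_px must be an increasing pair with min >= 3")
    }
    if (noise_sigma < 0) stop_parameter("noise_sigma must be non-negative")
  })
  invisible(p)
}

#' Render the radial intensity field of a laser spot
#'
#' The field equals `peak` at the centroid and decreases strictly
#' monotonically with radius: a gentle quadratic core, then a smooth
#' half-cosine intensity step of width `0.5 * radius` centred exactly on
#' the nominal radius `diameter_px / 2` (where the value is `edge`), then a
#' fast fade to zero at 1.5x the radius. Because the step is symmetric
#' about the nominal radius, its inflection -- the point of steepest
#' gradient that edge detectors localise -- stays at the nominal radius
#' under blurring, which is what defines the spot's ground-truth diameter
#' self-consistently.
#'
#' @param centroid Numeric `(row, col)` spot centre (may be fractional).
#' @param diameter_px Spot diameter in pixels, >= 3.
#' @param peak,edge Intensities at centre and at the nominal edge radius
#'   (`peak > edge`).
#' @param height,width Dimensions of the returned field.
#' @param step_amp Half-amplitude of the edge step about `edge`; the scene
#'   compositor passes `edge - trunk_intensity` so that the part of the
#'   step visible above the trunk stays symmetric about the nominal radius.
#'   Default `min(0.9 * (peak - edge), 0.95 * edge)`.
#' @return A `height x width` matrix, zero beyond 1.5x the spot radius.
#' @export
render_spot <- function(centroid, diameter_px, peak, edge, height, width,
                        step_amp = NULL) {
  if (diameter_px < 3) stop_parameter("degenerate spot: diameter_px must be >= 3")
  if (!(peak > edge)) stop_parameter("peak intensity must exceed edge intensity")
  r <- diameter_px / 2
  w <- 0.25 * r # half-width of the edge step
  amp <- step_amp %||% min(0.9 * (peak - edge), 0.95 * edge)
  amp <- clamp(amp, 0, min(0.95 * (peak - edge), edge))
  s1 <- edge + amp # intensity where the step begins (core boundary)
  s2 <- edge - amp # intensity where the step ends
  rows <- matrix(seq_len(height), height, width)
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  rho <- sqrt((rows - centroid[1])^2 + (cols - centroid[2])^2)
  f <- matrix(0, height, width)
  core <- rho <= r - w
  f[core] <- s1 + (peak - s1) * cos(pi * rho[core] / (2 * (r - w)))
  step <- rho > r - w & rho <= r + w
  f[step] <- edge + amp * cos(pi * (rho[step] - (r - w)) / (2 * w))
  fade <- rho > r + w & rho < 1.5 * r
  f[fade] <- s2 * cos(pi * (rho[fade] - (r + w)) / (2 * (0.5 * r - w)))^2
  f
}

# Smooth low-order polynomial shading surface with max|.| = amplitude.
# Coefficients are drawn from the current RNG stream.
illumination_surface <- function(height, width, amplitude) {
  if (amplitude <= 0) return(matrix(0, height, width))
  u <- (matrix(seq_len(width), height, width, byrow = TRUE) - 1) / (width - 1)
  v <- (matrix(seq_len(height), height, width) - 1) / (height - 1)
  a <- runif(4, -1, 1)
  g <- a[1] * u + a[2] * v + a[3] * u * v + a[4] * (u - 0.5)^2
  m <- max(abs(g))
  if (m < .Machine$double.eps) return(matrix(0, height, width))
  g / m * amplitude
}

#' Generate one synthetic scene with ground truth
#'
#' Composes background + illumination shading, the trunk band, the laser
#' spot, disturbing blobs (all bright structures composited with `pmax`),
#' and additive Gaussian noise clipped to \[0, 255\]. The returned truth
#' record echoes all parameters plus the true trunk pixel width at the spot
#' row.
#'
#' @param params A [scene_params()] object.
#' @return A list of class `stemspot_scene` with elements `image` (matrix,
#'   0-255), `trunk_mask` (matrix over \{0, 255\}) and `truth` (list).
#' @export
generate_scene <- function(params) {
  if (!inherits(params, "stemspot_scene_params")) {
    params <- do.call(scene_params, params)
  }
  validate_scene_params(params)
  p <- params
  h <- p$image_height_px; w <- p$image_width_px
  set.seed(p$seed)

  img <- matrix(p$background_intensity, h, w) +
    illumination_surface(h, w, p$illumination_gradient_amplitude)

  # trunk band: exactly trunk_width_px columns centred on trunk_center_col_px
  c0 <- p$trunk_center_col_px - floor((p$trunk_width_px - 1) / 2)
  c1 <- c0 + p$trunk_width_px - 1
  cols <- max(1L, c0):min(w, c1)
  img[, cols] <- p$trunk_intensity +
    (img[, cols] - p$background_intensity) # keep the same shading offset

  mask <- matrix(0, h, w)
  mask[, cols] <- 255

  spot <- render_spot(p$spot_centroid, p$spot_diameter_px,
                      p$spot_peak_intensity, p$spot_edge_intensity, h, w,
                      step_amp = p$spot_edge_intensity - p$trunk_intensity)
  img <- pmax(img, spot)

  blobs <- list()
  if (p$n_disturbing_blobs > 0) {
    border <- max(4, round(0.10 * min(h, w)))
    # spot bounding box inflated to the full rendered support
    sr <- 1.5 * p$spot_diameter_px / 2
    bb <- c(p$spot_centroid[1] - sr, p$spot_centroid[1] + sr,
            p$spot_centroid[2] - sr, p$spot_centroid[2] + sr)
    for (i in seq_len(p$n_disturbing_blobs)) {
      d <- runif(1, p$blob_diameter_range_px[1], p$blob_diameter_range_px[2])
      peak <- runif(1, 160, 255)
      for (try in 1:100) {
        # biased toward edges: positions restricted to the border band
        side <- sample.int(4L, 1L)
        br <- switch(side,
          runif(1, 1, border),                      # top
          runif(1, h - border, h),                  # bottom
          runif(1, 1, h),                           # left
          runif(1, 1, h))                           # right
        bc <- switch(side,
          runif(1, 1, w),
          runif(1, 1, w),
          runif(1, 1, border),
          runif(1, w - border, w))
        inside_bb <- br >= bb[1] - d && br <= bb[2] + d &&
          bc >= bb[3] - d && bc <= bb[4] + d
        if (!inside_bb) break
      }
      blobs[[i]] <- list(centroid = c(br, bc), diameter_px = d, peak = peak)
      img <- pmax(img, render_spot(c(br, bc), max(d, 3), peak, 0.4 * peak, h, w))
    }
  }

  if (p$noise_sigma > 0) {
    img <- img + matrix(rnorm(h * w, 0, p$noise_sigma), h, w)
  }
  img <- clamp(img, 0, 255)

  truth <- list(
    params = p,
    spot_centroid = p$spot_centroid,
    spot_diameter_px = p$spot_diameter_px,
    trunk_width_px = length(cols),
    true_width_at_spot_row = length(cols),
    trunk_cols = range(cols),
    blobs = blobs
  )
  structure(list(image = img, trunk_mask = mask, truth = truth),
            class = "stemspot_scene")
}

#' Default parameter ranges for dataset generation
#'
#' The study conditions used by the package's seeded experiments: quarter
#' scale 480 x 270 frames, trunk widths 60-160 px, spot diameters 12-24 px,
#' up to 5 disturbing blobs, shading amplitude up to 30 gray levels and
#' sensor noise sigma 1-3. The spot sits near the frame centre (coaxial
#' laser), its row between 40 and 60% of the frame height.
#'
#' @return Named list of ranges (length-2 numeric) and fixed values.
#' @export
default_scene_ranges <- function() {
  list(
    image_height_px = 270L,
    image_width_px = 480L,
    trunk_width_px = c(60, 160),
    trunk_center_frac = c(0.42, 0.58),
    trunk_intensity = c(70, 95),
    background_intensity = c(30, 55),
    illumination_gradient_amplitude = c(0, 30),
    spot_row_frac = c(0.40, 0.60),
    spot_diameter_px = c(12, 24),
    spot_peak_intensity = c(230, 255),
    spot_edge_offset = c(40, 60), # spot edge intensity above the trunk level
    n_disturbing_blobs = c(0, 5),
    blob_diameter_range_px = c(3, 9),
    noise_sigma = c(1, 3)
  )
}

#' Generate a seeded dataset of synthetic scenes
#'
#' Draws `n` parameter sets uniformly from the given ranges, generates the
#' scenes, and records every drawn parameter in a manifest. Deterministic
#' under `seed`.
#'
#' @param n Number of scenes (>= 1).
#' @param param_ranges Ranges as in [default_scene_ranges()]; entries given
#'   there can be overridden individually.
#' @param seed Integer master seed.
#' @return List with `scenes` (list of [generate_scene()] results) and
#'   `manifest` (data frame, one row per scene, all drawn parameters).
#' @export
generate_dataset <- function(n, param_ranges = list(), seed = 1L) {
  if (!is_count(n) || n < 1) stop_parameter("n must be a positive integer")
  rg <- utils::modifyList(default_scene_ranges(), param_ranges)
  for (nm in names(rg)) {
    v <- rg[[nm]]
    if (length(v) == 2 && is.numeric(v) && v[2] < v[1]) {
      stop_parameter(sprintf("empty range for %s", nm))
    }
  }
  set.seed(seed)
  scene_seeds <- sample.int(.Machine$integer.max, n)
  draw <- function(range) if (length(range) == 1) range else runif(1, range[1], range[2])
  scenes <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    h <- as.integer(draw(rg$image_height_px))
    w <- as.integer(draw(rg$image_width_px))
    trunk_w <- round(draw(rg$trunk_width_px))
    trunk_c <- round(w * draw(rg$trunk_center_frac))
    spot_d <- draw(rg$spot_diameter_px)
    spot_row <- h * draw(rg$spot_row_frac)
    # spot column jittered inside the trunk band with a 2 px safety margin
    max_off <- max(0, trunk_w / 2 - spot_d / 2 - 2)
    spot_col <- trunk_c + runif(1, -max_off, max_off)
    trunk_i <- draw(rg$trunk_intensity)
    peak_i <- draw(rg$spot_peak_intensity)
    edge_i <- min(trunk_i + draw(rg$spot_edge_offset), peak_i - 20)
    p <- scene_params(
      image_height_px = h, image_width_px = w,
      trunk_width_px = trunk_w, trunk_center_col_px = trunk_c,
      trunk_intensity = trunk_i,
      background_intensity = draw(rg$background_intensity),
      illumination_gradient_amplitude = draw(rg$illumination_gradient_amplitude),
      spot_centroid = c(spot_row, spot_col),
      spot_diameter_px = spot_d,
      spot_peak_intensity = peak_i,
      spot_edge_intensity = edge_i,
      n_disturbing_blobs = round(draw(rg$n_disturbing_blobs)),
      blob_diameter_range_px = rg$blob_diameter_range_px,
      noise_sigma = draw(rg$noise_sigma),
      seed = scene_seeds[i]
    )
    scenes[[i]] <- generate_scene(p)
    rows[[i]] <- data.frame(
      scene_id = i, seed = scene_seeds[i],
      image_height_px = h, image_width_px = w,
      trunk_width_px = trunk_w, trunk_center_col_px = trunk_c,
      trunk_intensity = p$trunk_intensity,
      background_intensity = p$background_intensity,
      illumination_gradient_amplitude = p$illumination_gradient_amplitude,
      spot_row = spot_row, spot_col = spot_col,
      spot_diameter_px = spot_d,
      spot_peak_intensity = p$spot_peak_intensity,
      spot_edge_intensity = p$spot_edge_intensity,
      n_disturbing_blobs = p$n_disturbing_blobs,
      noise_sigma = p$noise_sigma
    )
  }
  list(scenes = scenes, manifest = do.call(rbind, rows))
}
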