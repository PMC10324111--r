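# Spot Detection Algorithm (SDA).
#
# The laser spot is recovered in four steps: (1) a grayscale opening removes
# small bright structures, so the positive difference original - opened (a
# white top-hat) enhances the spot and other small blobs -- the "circular
# structural elements" (CSE); each pass ends with a centre crop to 15/16 of
# the frame, discarding border clutter, and the pass is applied exactly
# twice; (2) among the remaining components the spot is the one closest to
# the frame centre (the laser is coaxial with the sensor); (3) the component
# centroid is translated back into original-image coordinates by the exact
# accumulated crop offset; (4) edge pixels on the spot's high-gradient ring
# are collected along radial spokes and a least-squares circle gives the
# spot's pixel diameter.

#' Grayscale morphological opening with a disk element
#'
#' Erosion followed by dilation with the same disk structuring element; the
#' result is pixelwise less than or equal to the input.
#'
#' @param img Gray image matrix (0-255).
#' @param selem_radius_px Disk radius in pixels (>= 1, and less than half the
#'   smaller image dimension).
#' @return Opened image matrix.
#' @export
sda_opening <- function(img, selem_radius_px) {
  assert_gray_image(img)
  if (!is_count(selem_radius_px) || selem_radius_px < 1) {
    stop_parameter("selem_radius_px must be a positive integer")
  }
  if (selem_radius_px >= min(dim(img)) / 2) {
    stop_parameter("selem_radius_px must be smaller than half the image size")
  }
  brush <- EBImage::makeBrush(2 * selem_radius_px + 1, shape = "disc")
  out <- EBImage::opening(EBImage::Image(img / 255), kern = brush)
  matrix(as.numeric(out) * 255, nrow(img), ncol(img))
}

#' Extract circular structural elements (CSE)
#'
#' Labels the connected components of the thresholded positive difference
#' `original - opened` (a white top-hat). The difference is binarised at
#' its mean plus three standard deviations (robust against sensor-noise
#' residue in the top-hat) and components smaller than `min_area_px` are
#' discarded. Component centroids are intensity-weighted by the difference
#' values.
#'
#' @param original Gray image matrix.
#' @param opened The opened image (same dimensions), or `NULL` when
#'   `original` is already a difference image.
#' @param min_area_px Minimum component area kept, pixels.
#' @return Object of class `stemspot_cse`: list with `components` (each a
#'   list with `centroid`, `area_px`, `pixels`), `image_centroid`,
#'   `crop_offset` and `dim`.
#' @export
extract_cse <- function(original, opened = NULL, min_area_px = 9L) {
  assert_gray_image(original, "original")
  if (!is.null(opened)) {
    if (!identical(dim(original), dim(opened))) {
      stop_shape("original and opened images must have identical dimensions")
    }
    diffimg <- pmax(original - opened, 0)
  } else {
    diffimg <- original
  }
  thr <- mean(diffimg) + 3 * stats::sd(diffimg)
  bw <- diffimg > thr
  comps <- list()
  if (any(bw)) {
    lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
    lab <- matrix(as.integer(lab), nrow(original), ncol(original))
    for (id in seq_len(max(lab))) {
      pix <- which(lab == id, arr.ind = TRUE)
      if (nrow(pix) < min_area_px) next
      wts <- diffimg[pix]
      comps[[length(comps) + 1]] <- list(
        centroid = c(sum(pix[, 1] * wts), sum(pix[, 2] * wts)) / sum(wts),
        area_px = nrow(pix),
        pixels = pix
      )
    }
  }
  structure(list(
    components = comps,
    image_centroid = c((nrow(original) + 1) / 2, (ncol(original) + 1) / 2),
    crop_offset = c(0, 0),
    dim = dim(original)
  ), class = "stemspot_cse")
}

#' Central crop to 15/16 of each linear dimension
#'
#' Each dimension is scaled by 15/16 (floor); the removed margin is split
#' evenly between the two sides with the extra pixel going to the leading
#' (top/left) side, and the accumulated translation offset is updated so
#' that content at original position `(r, c)` appears at
#' `(r - offset[1], c - offset[2])`.
#'
#' @param img Gray image matrix, at least 16 px in each dimension.
#' @param offset Accumulated `(row, col)` translation before this crop.
#' @return List with `image` (cropped matrix) and `offset` (updated).
#' @export
crop_step <- function(img, offset = c(0, 0)) {
  assert_gray_image(img)
  h <- nrow(img); w <- ncol(img)
  if (h < 16 || w < 16) stop_parameter("image must be at least 16 px in each dimension")
  nh <- floor(h * 15 / 16); nw <- floor(w * 15 / 16)
  top <- ceiling((h - nh) / 2); left <- ceiling((w - nw) / 2)
  list(image = img[top + seq_len(nh), left + seq_len(nw), drop = FALSE],
       offset = c(offset[1] + top, offset[2] + left))
}

#' Select the spot component from a CSE set
#'
#' Returns the component whose centroid minimises the Euclidean distance to
#' the current frame centroid; ties are broken by larger area, then by
#' row-major centroid order.
#'
#' @param cse A [extract_cse()] result.
#' @return The selected component (list with `centroid`, `area_px`, `pixels`).
#' @export
select_spot_component <- function(cse) {
  if (!inherits(cse, "stemspot_cse")) stop_parameter("cse must be a stemspot_cse object")
  if (length(cse$components) == 0) stop_no_spot("no spot: CSE set is empty")
  cent <- t(vapply(cse$components, `[[`, numeric(2), "centroid"))
  d <- sqrt((cent[, 1] - cse$image_centroid[1])^2 +
              (cent[, 2] - cse$image_centroid[2])^2)
  area <- vapply(cse$components, `[[`, numeric(1), "area_px")
  ord <- order(d, -area, cent[, 1], cent[, 2])
  cse$components[[ord[1]]]
}

#' Correct a cropped-frame centroid back to original coordinates
#'
#' Realises the crop-invariance correction as the exact cumulative crop
#' translation: `original = cropped + offset`.
#'
#' @param centroid `(row, col)` in the cropped frame.
#' @param crop_offset Accumulated `(row, col)` translation from [crop_step()].
#' @return `(row, col)` in original-image coordinates.
#' @export
correct_centroid <- function(centroid, crop_offset) {
  as.numeric(centroid) + as.numeric(crop_offset)
}

#' Intensity statistics of a gray image
#'
#' @param img Gray image matrix.
#' @param eta Label value assigned to above-threshold pixels (0 < eta <= 255);
#'   defaults to the maximum gray level.
#' @return List of class `stemspot_gray_stats` with `mu`, `sigma`, `eta`.
#' @export
gray_stats <- function(img, eta = 255) {
  assert_gray_image(img)
  if (eta <= 0 || eta > 255) stop_parameter("eta must lie in (0, 255]")
  structure(list(mu = mean(img), sigma = stats::sd(img), eta = eta),
            class = "stemspot_gray_stats")
}

#' Threshold an image at the mean-shifted half label value
#'
#' Pixels with `p > eta/2 + mu` are assigned `eta`, all others 0. With the
#' default `eta = 255` this labels pixels brighter than the image mean plus
#' half the maximum gray level -- the bright spot core.
#'
#' @param img Gray image matrix.
#' @param stats A [gray_stats()] object computed from `img`.
#' @return Matrix over \{0, eta\}.
#' @export
threshold_spot <- function(img, stats) {
  assert_gray_image(img)
  if (!inherits(stats, "stemspot_gray_stats")) {
    stop_parameter("stats must be a stemspot_gray_stats object")
  }
  out <- matrix(0, nrow(img), ncol(img))
  out[img > stats$eta / 2 + stats$mu] <- stats$eta
  out
}

#' Select spot edge points on the high-gradient ring
#'
#' Casts `n_rays` radial spokes from the centroid through a window around
#' the thresholded spot core and places one edge point per spoke at the
#' radius of maximum Sobel gradient magnitude (parabolic sub-pixel
#' refinement). Spokes whose peak gradient falls below
#' `min_gradient_frac` times the median peak, or whose maximum lies at the
#' sampling boundary, are discarded; relaxing `min_gradient_frac` towards 0
#' monotonically grows the returned point count.
#'
#' @param img Gray image matrix (the original image).
#' @param spot_region Binary matrix (non-zero = candidate spot core pixels),
#'   e.g. from [threshold_spot()].
#' @param centroid Spot centroid `(row, col)` in `img` coordinates.
#' @param n_rays Number of radial spokes.
#' @param min_gradient_frac Acceptance fraction of the median per-spoke peak
#'   gradient, in \[0, 1\].
#' @param smooth_sigma Gaussian pre-smoothing sigma, pixels; 0 (default)
#'   relies on the Sobel operator's own smoothing, which the multi-ray
#'   average makes sufficient even under strong sensor noise.
#' @return A `k x 2` matrix of `(row, col)` edge points (`k >= 3`), with the
#'   per-point radius in attribute `"radius"`.
#' @export
select_edge_points <- function(img, spot_region, centroid, n_rays = 72L,
                               min_gradient_frac = 0.5, smooth_sigma = 0) {
  assert_gray_image(img)
  if (!any(spot_region > 0)) stop_insufficient_edge("spot_region is empty")

  # keep only the core component nearest the centroid
  lab <- EBImage::bwlabel(EBImage::Image((spot_region > 0) * 1))
  lab <- matrix(as.integer(lab), nrow(img), ncol(img))
  best <- NULL; best_d <- Inf
  for (id in seq_len(max(lab))) {
    pix <- which(lab == id, arr.ind = TRUE)
    ctr <- colMeans(pix)
    d <- sqrt(sum((ctr - centroid)^2))
    if (d < best_d) { best_d <- d; best <- pix }
  }
  core_d <- 2 * sqrt(nrow(best) / pi) # equivalent core diameter
  rmax <- max(6, 1.5 * core_d)
  # adapt the pre-smoothing to the spot scale: a fixed sigma comparable to
  # the edge-step width of small spots would blur their gradient ring inward
  smooth_sigma <- min(smooth_sigma, max(0.5, core_d / 16))

  # crop a window around the centroid for smoothing/gradient computation
  r0 <- max(1, floor(centroid[1] - rmax - 3)); r1 <- min(nrow(img), ceiling(centroid[1] + rmax + 3))
  c0 <- max(1, floor(centroid[2] - rmax - 3)); c1 <- min(ncol(img), ceiling(centroid[2] + rmax + 3))
  win <- img[r0:r1, c0:c1, drop = FALSE]
  g <- sobel_magnitude(gaussian_blur(win, smooth_sigma))
  ctr_w <- c(centroid[1] - r0 + 1, centroid[2] - c0 + 1)

  step <- 0.25
  radii <- seq(max(1, 0.25 * core_d), rmax, by = step)
  theta <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  pts <- matrix(NA_real_, n_rays, 2)
  rad <- rep(NA_real_, n_rays)
  peak <- rep(NA_real_, n_rays)
  for (j in seq_len(n_rays)) {
    rr <- ctr_w[1] + radii * sin(theta[j])
    cc <- ctr_w[2] + radii * cos(theta[j])
    inside <- rr >= 1 & rr <= nrow(g) & cc >= 1 & cc <= ncol(g)
    if (sum(inside) < 3) next
    prof <- bilinear_sample(g, rr[inside], cc[inside])
    i <- which.max(prof)
    if (i == 1 || i == length(prof)) next # boundary maxima are unreliable
    # parabolic sub-pixel refinement of the peak radius
    denom <- prof[i - 1] - 2 * prof[i] + prof[i + 1]
    shift <- if (abs(denom) > .Machine$double.eps) {
      clamp(0.5 * (prof[i - 1] - prof[i + 1]) / denom, -0.5, 0.5)
    } else 0
    rj <- radii[inside][i] + shift * step
    rad[j] <- rj
    peak[j] <- prof[i]
    pts[j, ] <- centroid + rj * c(sin(theta[j]), cos(theta[j]))
  }
  ok <- !is.na(peak)
  if (any(ok)) {
    ok <- ok & peak >= min_gradient_frac * stats::median(peak[ok])
  }
  if (sum(ok) >= 5) {
    # robust rejection of spokes that latched onto a stronger nearby edge
    # (e.g. the trunk contour): trim radii far from the median ring
    med <- stats::median(rad[ok])
    tol <- max(2 * stats::mad(rad[ok]), 0.1 * med, 1)
    ok <- ok & !is.na(rad) & abs(rad - med) <= tol
  }
  if (sum(ok) < 3) stop_insufficient_edge("fewer than 3 spot edge candidates")
  structure(pts[ok, , drop = FALSE], radius = rad[ok])
}

#' Least-squares circle fit of spot edge points
#'
#' The diameter estimator is twice the mean Euclidean distance of the k edge
#' points to the circle centre. By default one refinement pass re-estimates
#' the centre with an algebraic (Kasa) least-squares fit before applying the
#' mean-distance formula; the estimate anchored at the supplied centroid is
#' always reported alongside.
#'
#' @param edge_points `k x 2` matrix of `(row, col)` points, `k >= 3`.
#' @param centroid Spot centroid `(row, col)` anchoring the unrefined
#'   estimate.
#' @param refine Re-centre with a Kasa fit before estimating the diameter?
#' @return List with `diameter_px` (refined if `refine`), `rms_residual`
#'   (RMS of radial deviations about the fitted radius), `center` (centre
#'   used for `diameter_px`) and `diameter_px_centroid` (estimate anchored
#'   at `centroid`).
#' @export
fit_circle <- function(edge_points, centroid, refine = TRUE) {
  pts <- as.matrix(edge_points)
  if (nrow(pts) < 3) stop_insufficient_edge("circle fit needs at least 3 edge points")
  d_centroid <- 2 * mean(sqrt((pts[, 1] - centroid[1])^2 + (pts[, 2] - centroid[2])^2))
  center <- as.numeric(centroid)
  if (refine) {
    # Kasa algebraic fit: x^2 + y^2 = 2 a x + 2 b y + c
    a_mat <- cbind(2 * pts[, 1], 2 * pts[, 2], 1)
    rhs <- pts[, 1]^2 + pts[, 2]^2
    sol <- tryCatch(qr.solve(a_mat, rhs), error = function(e) NULL)
    if (!is.null(sol)) center <- sol[1:2]
  }
  radii <- sqrt((pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2)
  diameter <- 2 * mean(radii)
  list(diameter_px = diameter,
       rms_residual = sqrt(mean((radii - mean(radii))^2)),
       center = center,
       diameter_px_centroid = d_centroid)
}

#' SDA configuration
#'
#' @param selem_radius_px Disk radius of the opening element; `NULL` scales
#'   with the frame as `max(3, round(min(H, W) / 34))`.
#' @param min_area_px Minimum CSE component area.
#' @param eta Label value for [threshold_spot()].
#' @param n_rays,min_gradient_frac,smooth_sigma Edge selection parameters,
#'   see [select_edge_points()].
#' @param refine Kasa re-centring in [fit_circle()].
#' @return List of class `stemspot_sda_config`.
#' @export
sda_config <- function(selem_radius_px = NULL, min_area_px = 9L, eta = 255,
                       n_rays = 72L, min_gradient_frac = 0.5,
                       smooth_sigma = 0, refine = TRUE) {
  structure(list(selem_radius_px = selem_radius_px, min_area_px = min_area_px,
                 eta = eta, n_rays = n_rays,
                 min_gradient_frac = min_gradient_frac,
                 smooth_sigma = smooth_sigma, refine = refine),
            class = "stemspot_sda_config")
}

#' Run the full spot detection algorithm
#'
#' Applies the opening / positive-difference / centre-crop pass exactly
#' twice (balancing spot enhancement against suppression of disturbing
#' factors), labels the remaining circular structural elements, selects the
#' component closest to the frame centre, corrects its centroid back to
#' original coordinates, and fits a circle to the gradient-selected edge
#' ring of the spot in the original image.
#'
#' @param img Gray image matrix (0-255).
#' @param config A [sda_config()] object.
#' @return Object of class `stemspot_spotfit`: list with `centroid`
#'   (corrected, original coordinates), `edge_points`, `k`, `diameter_px`,
#'   `diameter_px_centroid`, `fit_rms_residual`, `fit_center` and
#'   `crop_offset`.
#' @export
run_sda <- function(img, config = sda_config()) {
  assert_gray_image(img)
  cfg <- config
  r <- cfg$selem_radius_px
  if (is.null(r)) r <- max(3L, round(min(dim(img)) / 34))

  work <- img
  offset <- c(0, 0)
  for (i in 1:2) {
    opened <- sda_opening(work, r)
    d <- pmax(work - opened, 0)
    cs <- crop_step(d, offset)
    work <- cs$image
    offset <- cs$offset
  }

  cse <- extract_cse(work, NULL, min_area_px = cfg$min_area_px)
  if (length(cse$components) == 0) {
    stop_no_spot("no spot found [stage: component selection]")
  }
  comp <- select_spot_component(cse)
  centroid <- correct_centroid(comp$centroid, offset)

  gs <- gray_stats(img, eta = cfg$eta)
  core <- threshold_spot(img, gs)
  if (!any(core > 0)) {
    stop_no_spot("no spot found [stage: intensity thresholding]")
  }
  # refine the centroid on the thresholded spot core: the intensity
  # threshold separates the spot from disturbing factors more precisely
  # than the top-hat components, whose cap can merge with clutter
  lab <- EBImage::bwlabel(EBImage::Image((core > 0) * 1))
  lab <- matrix(as.integer(lab), nrow(img), ncol(img))
  best <- NULL; best_d <- Inf
  for (id in seq_len(max(lab))) {
    pix <- which(lab == id, arr.ind = TRUE)
    d0 <- sqrt(sum((colMeans(pix) - centroid)^2))
    if (d0 < best_d) { best_d <- d0; best <- pix }
  }
  if (!is.null(best) && nrow(best) >= cfg$min_area_px) {
    wts <- img[best] - min(img[best]) + 1
    refined <- c(sum(best[, 1] * wts), sum(best[, 2] * wts)) / sum(wts)
    core_d <- 2 * sqrt(nrow(best) / pi)
    if (best_d <= 1.5 * core_d) centroid <- refined
  }
  pts <- withCallingHandlers(
    select_edge_points(img, core, centroid, n_rays = cfg$n_rays,
                       min_gradient_frac = cfg$min_gradient_frac,
                       smooth_sigma = cfg$smooth_sigma),
    error = function(e) {
      if (inherits(e, "stemspot_insufficient_edge_error")) {
        stop_insufficient_edge(paste0(conditionMessage(e), " [stage: edge selection]"))
      }
    })
  fit <- fit_circle(pts, centroid, refine = cfg$refine)

  structure(list(
    centroid = centroid,
    edge_points = pts,
    k = nrow(pts),
    diameter_px = fit$diameter_px,
    diameter_px_centroid = fit$diameter_px_centroid,
    fit_rms_residual = fit$rms_residual,
    fit_center = fit$center,
    crop_offset = offset
  ), class = "stemspot_spotfit")
}
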