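# Trunk segmentation post-processing and the deterministic baseline.
#
# The baseline segmenter thresholds the image globally (Otsu), keeps the
# largest connected component on the side of the threshold that best covers
# the central column band (the trunk may be brighter or darker than the
# background), and fills holes. It makes the geometry pipeline testable
# without any training; the learned segmenter lives in net-model.R.

#' Deterministic baseline trunk segmenter
#'
#' Global Otsu threshold, selection of the polarity (foreground above or
#' below the threshold) whose largest connected component best covers the
#' central columns of the frame, followed by hole filling.
#'
#' @param img Gray image matrix (0-255).
#' @return Trunk mask matrix over \{0, 255\}.
#' @export
segment_threshold <- function(img) {
  assert_gray_image(img)
  if (stats::sd(img) < 1e-8) stop_no_trunk("no trunk: image has no contrast")
  thr <- EBImage::otsu(EBImage::Image(img / 255)) * 255

  central <- seq(floor(ncol(img) * 0.4), ceiling(ncol(img) * 0.6))
  candidate <- function(fg) {
    if (!any(fg)) return(NULL)
    lab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(fg * 1))),
                  nrow(img), ncol(img))
    areas <- tabulate(lab[lab > 0])
    best <- which.max(areas)
    comp <- lab == best
    list(mask = comp, score = sum(comp[, central]))
  }
  hi <- candidate(img > thr)
  lo <- candidate(img <= thr)
  pick <- NULL
  if (!is.null(hi) && (is.null(lo) || hi$score >= lo$score)) pick <- hi
  else if (!is.null(lo)) pick <- lo
  if (is.null(pick) || pick$score == 0) stop_no_trunk("no trunk: empty foreground")

  filled <- EBImage::fillHull(EBImage::Image(pick$mask * 1))
  mask <- matrix(as.numeric(filled), nrow(img), ncol(img))
  mask * 255
}

#' Binarise a saliency map to a trunk mask
#'
#' @param map Saliency matrix with values in \[0, 1\].
#' @param threshold Cut value in (0, 1); default 0.5.
#' @return Trunk mask matrix over \{0, 255\}.
#' @export
binarize_saliency <- function(map, threshold = 0.5) {
  if (!is.matrix(map) || min(map) < 0 || max(map) > 1) {
    stop_parameter("map must be a matrix with values in [0, 1]")
  }
  if (threshold <= 0 || threshold >= 1) stop_parameter("threshold must lie in (0, 1)")
  (map > threshold) * 255
}

#' Per-row foreground width at a reference column
#'
#' For every image row, the length of the contiguous foreground run that
#' contains `reference_col` (0 where the reference column is background).
#'
#' @param mask Binary trunk mask (non-zero = foreground).
#' @param reference_col Column index anchoring the run.
#' @return Object of class `stemspot_width_profile`: list with `width_px`
#'   (numeric vector, one entry per row), `rows` and `reference_col`.
#' @export
width_profile <- function(mask, reference_col) {
  if (!is.matrix(mask)) stop_shape("mask must be a matrix")
  h <- nrow(mask); w <- ncol(mask)
  ref <- as.integer(round(reference_col))
  if (ref < 1 || ref > w) stop_parameter("reference_col outside the mask")
  fg <- mask > 0
  widths <- numeric(h)
  for (r in seq_len(h)) {
    if (!fg[r, ref]) next
    row <- fg[r, ]
    left <- ref
    while (left > 1 && row[left - 1]) left <- left - 1
    right <- ref
    while (right < w && row[right + 1]) right <- right + 1
    widths[r] <- right - left + 1
  }
  structure(list(width_px = widths, rows = seq_len(h), reference_col = ref),
            class = "stemspot_width_profile")
}

#' Locate the measurement row on the width profile
#'
#' In `"trunk"` mode (large trees, no branching near the spot) the spot row
#' itself is used. In `"sapling"` mode the stem is measured below the
#' branching point: the profile is smoothed with a running mean and the
#' bottom-most run of rows whose relative row-to-row width change stays
#' within `stability_tol` is located; its first (topmost) row is returned,
#' or `spot_row` when that run already covers it. When no stable region
#' exists the function falls back to `spot_row` with a warning.
#'
#' @param profile A [width_profile()] object.
#' @param spot_row Row of the detected spot.
#' @param mode `"trunk"` or `"sapling"`.
#' @param stability_tol Maximum relative width change per row in the stable
#'   region.
#' @param smooth_window Running-mean window (odd), rows.
#' @return A row index within the profile bounds.
#' @export
find_measurement_row <- function(profile, spot_row,
                                 mode = c("trunk", "sapling"),
                                 stability_tol = 0.05, smooth_window = 9L) {
  mode <- match.arg(mode)
  if (!inherits(profile, "stemspot_width_profile")) {
    stop_parameter("profile must be a stemspot_width_profile object")
  }
  h <- length(profile$width_px)
  spot_row <- clamp(as.integer(round(spot_row)), 1L, h)
  if (mode == "trunk") return(spot_row)

  w <- profile$width_px
  half <- smooth_window %/% 2
  sm <- stats::filter(w, rep(1 / smooth_window, smooth_window), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- w[is.na(sm)]
  rel <- c(0, abs(diff(sm)) / pmax(sm[-length(sm)], 1))
  stable <- sm > 0 & rel <= stability_tol
  runs <- rle(stable)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  good <- which(runs$values & runs$lengths >= smooth_window)
  if (length(good) == 0) {
    warning("no stable stem region found; falling back to the spot row")
    return(spot_row)
  }
  g <- good[length(good)] # bottom-most stable run
  if (spot_row >= starts[g] && spot_row <= ends[g]) return(spot_row)
  # skip the smoothing transient at the run head
  clamp(starts[g] + half, starts[g], ends[g])
}
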