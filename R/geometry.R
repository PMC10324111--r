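# Scale-reference geometry: pixel quantities to physical stem diameter.
#
# The laser spot of known physical diameter R (mm) is imaged together with
# the trunk, so pixel and physical lengths are proportional at the trunk
# plane: S'/S = R'/R. All conversions live here; R is in mm, outputs S and
# h in cm, pixel quantities in px. The slight optical distortion induced by
# the sensor-laser angle (nominally 91 degrees) is neglected -- it hardly
# affects the calculation at the device's working distances.

#' Device configuration
#'
#' @param spot_diameter_mm Physical laser spot diameter R, 3.00-30.00 mm.
#' @param sensor_laser_angle_deg Angle between sensor axis and laser beam;
#'   must lie in (85, 95) (distortion neglected).
#' @param working_distance_range_m Informational working range, metres.
#' @return List of class `stemspot_device_config`.
#' @export
device_config <- function(spot_diameter_mm = 30,
                          sensor_laser_angle_deg = 91,
                          working_distance_range_m = c(0.05, 30)) {
  if (spot_diameter_mm < 3 || spot_diameter_mm > 30) {
    stop_parameter("spot_diameter_mm must lie in [3.00, 30.00] mm")
  }
  if (sensor_laser_angle_deg <= 85 || sensor_laser_angle_deg >= 95) {
    stop_parameter("sensor_laser_angle_deg must lie in (85, 95)")
  }
  structure(list(spot_diameter_mm = spot_diameter_mm,
                 sensor_laser_angle_deg = sensor_laser_angle_deg,
                 working_distance_range_m = working_distance_range_m),
            class = "stemspot_device_config")
}

#' Stem diameter from pixel widths and the spot scale reference
#'
#' `S = S' * R / R'`, with R in mm and the result in cm.
#'
#' @param stem_width_px Trunk width S' in pixels.
#' @param spot_diameter_px Spot diameter R' in pixels.
#' @param spot_diameter_mm Physical spot diameter R in mm.
#' @return Stem diameter S in cm.
#' @export
stem_diameter <- function(stem_width_px, spot_diameter_px, spot_diameter_mm) {
  if (any(c(stem_width_px, spot_diameter_px, spot_diameter_mm) <= 0)) {
    stop_measurement("stem_diameter requires positive S', R' and R")
  }
  stem_width_px * spot_diameter_mm / spot_diameter_px / 10
}

#' Convert any pixel length to centimetres via the spot scale
#'
#' Generalises the height relation `h'/R' = h/R`: any pixel length is
#' scaled by `R / R'` (mm per pixel) and returned in cm.
#'
#' @param length_px Length in pixels.
#' @param spot_diameter_px Spot diameter R' in pixels.
#' @param spot_diameter_mm Physical spot diameter R in mm.
#' @return Length in cm.
#' @export
pixel_to_physical <- function(length_px, spot_diameter_px, spot_diameter_mm) {
  if (spot_diameter_px <= 0 || spot_diameter_mm <= 0) {
    stop_measurement("non-positive scale: R' and R must be positive")
  }
  length_px * spot_diameter_mm / spot_diameter_px / 10
}

#' Measure the stem diameter in one image
#'
#' Full pipeline: spot detection ([run_sda()]), trunk segmentation (the
#' deterministic threshold baseline or the saliency network), per-row width
#' profile at the spot column, measurement-row selection, and the
#' pixel-to-physical conversion. All intermediate pixel quantities are
#' carried in the returned record.
#'
#' @param img Gray image matrix (0-255).
#' @param device A [device_config()].
#' @param segmenter `"threshold"` or `"unet"`.
#' @param mode Measurement-row mode, `"trunk"` (at the spot row) or
#'   `"sapling"` (below branching), see [find_measurement_row()].
#' @param net Trained `stemspot_net`, required when `segmenter = "unet"`.
#' @param sda A [sda_config()].
#' @param ground_row Optional image row of the ground line; when supplied
#'   the measurement height is reported via the `h'/R' = h/R` relation.
#' @param image_id,gps Optional identifiers copied into the record.
#' @return List of class `stemspot_measurement` with `stem_diameter_cm`,
#'   `height_cm` (or `NA`), `stem_width_px`, `spot_diameter_px`,
#'   `height_px`, `scale_mm_per_px`, `spot_centroid`, `measurement_row`,
#'   `image_id`, `gps` and `warnings`.
#' @export
measure <- function(img, device = device_config(),
                    segmenter = c("threshold", "unet"),
                    mode = c("trunk", "sapling"),
                    net = NULL, sda = sda_config(),
                    ground_row = NULL, image_id = NA_character_, gps = NULL) {
  segmenter <- match.arg(segmenter)
  mode <- match.arg(mode)
  assert_gray_image(img)
  warnings <- character(0)

  fit <- run_sda(img, sda)

  mask <- if (segmenter == "threshold") {
    segment_threshold(img)
  } else {
    if (is.null(net)) stop_parameter("segmenter = 'unet' requires a trained net")
    binarize_saliency(net_forward(net, img, fit$centroid)$fused)
  }

  sr <- clamp(round(fit$centroid[1]), 1, nrow(img))
  sc <- clamp(round(fit$centroid[2]), 1, ncol(img))
  if (mask[sr, sc] == 0) {
    warnings <- c(warnings, "spot centroid outside the trunk foreground")
  }

  profile <- width_profile(mask, sc)
  row <- withCallingHandlers(
    find_measurement_row(profile, sr, mode = mode),
    warning = function(cnd) {
      warnings <<- c(warnings, conditionMessage(cnd))
      invokeRestart("muffleWarning")
    })
  s_px <- profile$width_px[row]
  if (s_px <= 0) {
    # fall back to the widest row: the reference column must cross the trunk
    row <- which.max(profile$width_px)
    s_px <- profile$width_px[row]
    warnings <- c(warnings, "no trunk foreground at the measurement row; used widest row")
  }
  if (s_px <= 0) stop_no_trunk("no trunk: empty width profile")

  r_mm <- device$spot_diameter_mm
  s_cm <- stem_diameter(s_px, fit$diameter_px, r_mm)
  h_px <- if (!is.null(ground_row)) abs(ground_row - row) else NA_real_
  h_cm <- if (!is.null(ground_row)) {
    pixel_to_physical(h_px, fit$diameter_px, r_mm)
  } else NA_real_

  structure(list(
    stem_diameter_cm = s_cm,
    height_cm = h_cm,
    stem_width_px = s_px,
    spot_diameter_px = fit$diameter_px,
    height_px = h_px,
    scale_mm_per_px = r_mm / fit$diameter_px,
    spot_centroid = fit$centroid,
    measurement_row = row,
    segmenter = segmenter,
    mode = mode,
    image_id = image_id,
    gps = gps,
    warnings = warnings
  ), class = "stemspot_measurement")
}
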