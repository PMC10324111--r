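# Seeded recovery experiments on synthetic scenes.
#
# These are the package's reproducibility workhorses: they regenerate the
# study conditions from scratch under a caller-supplied seed, run the
# pipeline, and report per-scene and aggregate errors. Both the test suite
# and scripts/acceptance.R call them.

#' Spot-detection recovery experiment
#'
#' Generates `n` scenes with uneven illumination (amplitude 10-30 gray
#' levels) and 2-5 disturbing blobs, runs [run_sda()] on each, and reports
#' centroid and diameter errors against the generator truth.
#'
#' @param n Number of scenes.
#' @param seed Master seed.
#' @return List with `per_scene` (data frame: `centroid_error_px`,
#'   `diameter_error_pct`, `failed`) and `summary` (list: `success_rate_pct`
#'   of scenes with centroid error <= 2 px and diameter error <= 5%,
#'   plus mean/max errors).
#' @export
sda_recovery_experiment <- function(n = 200, seed = 1L) {
  ds <- generate_dataset(n, list(illumination_gradient_amplitude = c(10, 30),
                                 n_disturbing_blobs = c(2, 5)), seed = seed)
  rows <- lapply(seq_len(n), function(i) {
    sc <- ds$scenes[[i]]
    fit <- tryCatch(run_sda(sc$image), error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(scene = i, centroid_error_px = NA_real_,
                        diameter_error_pct = NA_real_, failed = TRUE))
    }
    data.frame(
      scene = i,
      centroid_error_px = sqrt(sum((fit$centroid - sc$truth$spot_centroid)^2)),
      diameter_error_pct = 100 * abs(fit$diameter_px - sc$truth$spot_diameter_px) /
        sc$truth$spot_diameter_px,
      failed = FALSE
    )
  })
  per_scene <- do.call(rbind, rows)
  ok <- !per_scene$failed & per_scene$centroid_error_px <= 2 &
    per_scene$diameter_error_pct <= 5
  list(per_scene = per_scene,
       summary = list(
         success_rate_pct = 100 * mean(ok),
         mean_centroid_error_px = mean(per_scene$centroid_error_px, na.rm = TRUE),
         max_centroid_error_px = max(per_scene$centroid_error_px, na.rm = TRUE),
         mean_diameter_error_pct = mean(per_scene$diameter_error_pct, na.rm = TRUE),
         max_diameter_error_pct = max(per_scene$diameter_error_pct, na.rm = TRUE)
       ))
}

#' End-to-end stem diameter recovery experiment
#'
#' Draws `n` true stem diameters uniformly across `diameter_range_cm`
#' (default 2-89 cm, the range observed in field use), maps each onto a
#' 640 x 360 scene through a plausible spot pixel diameter (14-18 px) with
#' the spot physical size chosen as in field practice (3 mm for stems below
#' 10 cm, 30 mm otherwise), runs the full pipeline ([measure()] with the
#' threshold segmenter), and reports relative errors plus the trend of
#' relative error with true diameter (one-sided test for a positive
#' correlation).
#'
#' The per-scene reference diameter is the one the rendered scene actually
#' realises (integer trunk width at the drawn spot scale), playing the role
#' of the tape measurement.
#'
#' @param n Number of scenes.
#' @param seed Master seed.
#' @param diameter_range_cm Range of true stem diameters.
#' @return List with `per_scene` (data frame: `true_cm`, `measured_cm`,
#'   `rel_error_pct`, `spot_mm`) and `summary` (list: `mean_abs_rel_error_pct`,
#'   `mae_cm`, `rmse_cm`, `r_squared`, `trend_cor`, `trend_p_value`,
#'   `n_failed`).
#' @export
diameter_recovery_experiment <- function(n = 100, seed = 1L,
                                         diameter_range_cm = c(2, 89)) {
  set.seed(seed)
  true_cm <- runif(n, diameter_range_cm[1], diameter_range_cm[2])
  spot_px <- runif(n, 14, 18)
  scene_seeds <- sample.int(.Machine$integer.max, n)
  h <- 360L; w <- 640L
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    r_mm <- if (true_cm[i] < 10) 3 else 30
    width_px <- round(true_cm[i] * 10 * spot_px[i] / r_mm)
    ref_cm <- width_px * r_mm / spot_px[i] / 10 # diameter the scene realises
    set.seed(scene_seeds[i])
    trunk_i <- runif(1, 80, 95)
    p <- scene_params(
      image_height_px = h, image_width_px = w,
      trunk_width_px = width_px,
      trunk_center_col_px = round(w / 2 + runif(1, -10, 10)),
      trunk_intensity = trunk_i,
      background_intensity = runif(1, 30, 50),
      illumination_gradient_amplitude = runif(1, 0, 20),
      spot_centroid = c(h * runif(1, 0.42, 0.58), w / 2 + runif(1, -8, 8)),
      spot_diameter_px = spot_px[i],
      spot_peak_intensity = 255,
      spot_edge_intensity = trunk_i + runif(1, 40, 60),
      n_disturbing_blobs = round(runif(1, 0, 3)),
      noise_sigma = runif(1, 1, 2),
      seed = scene_seeds[i]
    )
    sc <- generate_scene(p)
    rec <- tryCatch(
      measure(sc$image, device_config(spot_diameter_mm = r_mm),
              segmenter = "threshold"),
      error = function(e) NULL)
    rows[[i]] <- data.frame(
      scene = i, true_cm = ref_cm,
      measured_cm = if (is.null(rec)) NA_real_ else rec$stem_diameter_cm,
      spot_mm = r_mm
    )
  }
  per_scene <- do.call(rbind, rows)
  per_scene$rel_error_pct <- 100 *
    abs(per_scene$measured_cm - per_scene$true_cm) / per_scene$true_cm
  done <- !is.na(per_scene$measured_cm)
  em <- error_metrics(per_scene$measured_cm[done], per_scene$true_cm[done])
  trend <- stats::cor.test(per_scene$true_cm[done], per_scene$rel_error_pct[done],
                           alternative = "greater", method = "pearson")
  list(per_scene = per_scene,
       summary = list(
         mean_abs_rel_error_pct = mean(per_scene$rel_error_pct[done]),
         mae_cm = em$mae, rmse_cm = em$rmse, r_squared = em$r_squared,
         trend_cor = unname(trend$estimate),
         trend_p_value = trend$p.value,
         n_failed = sum(!done)
       ))
}

#' Brute-force circle fit oracle
#'
#' Independent grid-search reference for the circle estimator: a
#' coarse-to-fine scan over centre and radius minimising the summed squared
#' radial deviation. Slow and simple by design.
#'
#' @param pts `k x 2` matrix of edge points.
#' @param center0 Starting centre for the scan.
#' @param span Half-width of the initial centre scan, px.
#' @param levels Number of coarse-to-fine refinement levels.
#' @return List with `center`, `radius`, `diameter_px`.
#' @export
circle_fit_grid_oracle <- function(pts, center0, span = 3, levels = 4) {
  ctr <- as.numeric(center0)
  step <- span / 4
  for (lev in seq_len(levels)) {
    grid_r <- ctr[1] + seq(-span, span, by = step)
    grid_c <- ctr[2] + seq(-span, span, by = step)
    best <- NULL
    for (gr in grid_r) for (gc in grid_c) {
      rad <- sqrt((pts[, 1] - gr)^2 + (pts[, 2] - gc)^2)
      rr <- mean(rad) # optimal radius for fixed centre
      sse <- sum((rad - rr)^2)
      if (is.null(best) || sse < best$sse) {
        best <- list(center = c(gr, gc), radius = rr, sse = sse)
      }
    }
    ctr <- best$center
    span <- step
    step <- span / 4
  }
  list(center = best$center, radius = best$radius,
       diameter_px = 2 * best$radius)
}
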