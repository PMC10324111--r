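# Shared fixtures for the test suite: everything is generated in code.

# A clean scene: no noise, no blobs, no shading. Deterministic.
clean_scene <- function(spot_diameter_px = 16, seed = 1) {
  generate_scene(scene_params(
    noise_sigma = 0, n_disturbing_blobs = 0,
    illumination_gradient_amplitude = 0,
    spot_diameter_px = spot_diameter_px, seed = seed
  ))
}

# Brute-force intensity-weighted centroid of the largest above-threshold
# blob in a difference image; independent of extract_cse internals.
brute_weighted_centroid <- function(diffimg, thr) {
  pix <- which(diffimg > thr, arr.ind = TRUE)
  wts <- diffimg[diffimg > thr]
  c(sum(pix[, 1] * wts), sum(pix[, 2] * wts)) / sum(wts)
}

# Exact (brute-force) reference implementation of the weighted F-measure:
# same construction as the package version but with exact Euclidean
# nearest-foreground lookup; O(n_fg * n_bg), for small images only.
wfm_reference <- function(pred, truth, beta_sq = 0.3) {
  gt <- truth > 0.5 * max(1, max(truth))
  fm <- if (max(pred) > 1) pred / 255 else pred
  e <- abs(fm - gt)
  fgi <- which(gt, arr.ind = TRUE)
  bgi <- which(!gt, arr.ind = TRUE)
  d <- matrix(0, nrow(gt), ncol(gt))
  idx <- matrix(which(gt)[1], nrow(gt), ncol(gt))
  fg_lin <- which(gt)
  for (i in seq_len(nrow(bgi))) {
    dd <- sqrt((fgi[, 1] - bgi[i, 1])^2 + (fgi[, 2] - bgi[i, 2])^2)
    j <- which.min(dd)
    d[bgi[i, 1], bgi[i, 2]] <- dd[j]
    idx[bgi[i, 1], bgi[i, 2]] <- fg_lin[j]
  }
  et <- e
  et[!gt] <- e[idx[!gt]]
  k <- stemspot:::gaussian_kernel(7, 5)
  ea <- as.matrix(EBImage::filter2(EBImage::Image(et), k, boundary = "replicate"))
  min_e_ea <- e
  sel <- gt & (ea < e)
  min_e_ea[sel] <- ea[sel]
  b <- matrix(1, nrow(gt), ncol(gt))
  b[!gt] <- 2 - exp(log(0.5) / 5 * d[!gt])
  ew <- min_e_ea * b
  tpw <- sum(gt) - sum(ew[gt])
  fpw <- sum(ew[!gt])
  rw <- 1 - mean(ew[gt])
  pw <- tpw / (tpw + fpw + .Machine$double.eps)
  if (pw + rw == 0) return(0)
  (1 + beta_sq) * pw * rw / (beta_sq * pw + rw)
}

# Naive loop implementation of the error metrics (independent oracle).
error_metrics_loops <- function(measured, reference) {
  n <- length(measured)
  sae <- 0; sse <- 0
  for (i in seq_len(n)) {
    sae <- sae + abs(measured[i] - reference[i])
    sse <- sse + (measured[i] - reference[i])^2
  }
  list(mae = sae / n, mse = sse / n, rmse = sqrt(sse / n))
}
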