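# Evaluation metrics: segmentation quality (F-measure, weighted F-measure,
# S-measure, E-measure) and measurement accuracy (RE, MAE, MSE, RMSE, R^2).

#' F-measure from precision and recall
#'
#' `(1 + beta^2) P R / (beta^2 P + R)`. The saliency-benchmark convention
#' `beta^2 = 0.3` is the default. `P = R = 0` returns 0 with a warning.
#'
#' @param precision,recall Values in \[0, 1\].
#' @param beta_sq The beta-squared trade-off parameter (> 0).
#' @return The F-measure in \[0, 1\].
#' @export
f_measure <- function(precision, recall, beta_sq = 0.3) {
  if (beta_sq <= 0) stop_parameter("beta_sq must be positive")
  if (any(c(precision, recall) < 0) || any(c(precision, recall) > 1)) {
    stop_parameter("precision and recall must lie in [0, 1]")
  }
  if (precision + recall == 0) {
    warning("precision and recall are both zero; F-measure defined as 0")
    return(0)
  }
  (1 + beta_sq) * precision * recall / (beta_sq * precision + recall)
}

# Nearest-foreground-pixel index map by vectorised chamfer wavefront
# propagation (4-neighbour steps cost 1, diagonal sqrt(2)); returns the
# linear index of the closest truth pixel for every pixel.
nearest_fg_index <- function(fg) {
  h <- nrow(fg); w <- ncol(fg)
  idx <- matrix(NA_integer_, h, w)
  dist <- matrix(Inf, h, w)
  idx[fg] <- which(fg)
  dist[fg] <- 0
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  costs <- c(1, 1, 1, 1, sqrt(2), sqrt(2), sqrt(2), sqrt(2))
  repeat {
    changed <- FALSE
    for (s in seq_along(shifts)) {
      dr <- shifts[[s]][1]; dc <- shifts[[s]][2]
      src_r <- max(1, 1 - dr):min(h, h - dr)
      src_c <- max(1, 1 - dc):min(w, w - dc)
      cand <- dist[src_r, src_c, drop = FALSE] + costs[s]
      tgt_r <- src_r + dr; tgt_c <- src_c + dc
      cur <- dist[tgt_r, tgt_c, drop = FALSE]
      better <- cand < cur
      if (any(better)) {
        changed <- TRUE
        cur[better] <- cand[better]
        dist[tgt_r, tgt_c] <- cur
        src_idx <- idx[src_r, src_c, drop = FALSE]
        tgt_idx <- idx[tgt_r, tgt_c, drop = FALSE]
        tgt_idx[better] <- src_idx[better]
        idx[tgt_r, tgt_c] <- tgt_idx
      }
    }
    if (!changed) break
  }
  idx
}

gaussian_kernel <- function(size = 7, sigma = 5) {
  half <- (size - 1) / 2
  g <- outer(-half:half, -half:half, function(i, j) exp(-(i^2 + j^2) / (2 * sigma^2)))
  g / sum(g)
}

#' Weighted F-measure of a saliency map against a truth mask
#'
#' The dependency-weighted precision/recall construction: per-pixel errors
#' on the background are replaced by the error at the nearest foreground
#' pixel before Gaussian spreading, and background errors are down-weighted
#' by an exponential decay of the Euclidean distance to the foreground, so
#' errors far from the object count less and interdependent foreground
#' errors are not over-counted.
#'
#' @param pred Saliency matrix in \[0, 1\] (or a \{0, 255\} mask).
#' @param truth Truth mask over \{0, 255\} (or \{0, 1\}).
#' @param beta_sq Beta-squared of the final F combination.
#' @return The weighted F-measure in \[0, 1\].
#' @export
weighted_f_measure <- function(pred, truth, beta_sq = 0.3) {
  if (!identical(dim(pred), dim(truth))) stop_shape("pred and truth dimensions differ")
  gt <- truth > 0.5 * max(1, max(truth))
  if (!any(gt)) stop_metric("undefined metric: empty truth mask")
  fm <- if (max(pred) > 1) pred / 255 else pred

  e <- abs(fm - gt)
  idx <- nearest_fg_index(gt)
  # Euclidean distance of every background pixel to the foreground
  d <- as.matrix(EBImage::distmap(EBImage::Image(1 - gt * 1)))
  d[gt] <- 0

  et <- e
  et[!gt] <- e[idx[!gt]]
  k <- gaussian_kernel(7, 5)
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
  pw <- clamp(pw, 0, 1); rw <- clamp(rw, 0, 1)
  if (pw + rw == 0) return(0)
  (1 + beta_sq) * pw * rw / (beta_sq * pw + rw)
}

ssim_region <- function(x, y) {
  n <- length(x)
  if (n == 0) return(1)
  mx <- mean(x); my <- mean(y)
  vx <- if (n > 1) sum((x - mx)^2) / (n - 1) else 0
  vy <- if (n > 1) sum((y - my)^2) / (n - 1) else 0
  vxy <- if (n > 1) sum((x - mx) * (y - my)) / (n - 1) else 0
  a <- 4 * mx * my * vxy
  b <- (mx^2 + my^2) * (vx + vy)
  if (a != 0) a / (b + .Machine$double.eps)
  else if (a == 0 && b == 0) 1
  else 0
}

object_score <- function(x) {
  mx <- mean(x)
  sx <- stats::sd(x)
  if (is.na(sx)) sx <- 0
  2 * mx / (mx^2 + 1 + 2 * sx + .Machine$double.eps)
}

#' Structure measure (S-measure) of a saliency map
#'
#' Convex combination (weight 0.5) of an object-aware similarity
#' (foreground/background contrast-and-dispersion scores, mixed by the
#' foreground fraction) and a region-aware similarity (per-quadrant SSIM
#' about the truth centroid, weighted by quadrant area).
#'
#' @param pred Saliency matrix in \[0, 1\] (or a \{0, 255\} mask).
#' @param truth Truth mask over \{0, 255\} (or \{0, 1\}).
#' @param alpha Mixing weight of the object-aware term.
#' @return The S-measure, clamped to \[0, 1\].
#' @export
s_measure <- function(pred, truth, alpha = 0.5) {
  if (!identical(dim(pred), dim(truth))) stop_shape("pred and truth dimensions differ")
  gt <- truth > 0.5 * max(1, max(truth))
  if (!any(gt)) stop_metric("undefined metric: empty truth mask")
  fm <- if (max(pred) > 1) pred / 255 else pred

  mu <- mean(gt)
  s_object <- mu * object_score(fm[gt]) + (1 - mu) * object_score(1 - fm[!gt])

  # region-aware: split about the truth centroid
  pix <- which(gt, arr.ind = TRUE)
  cr <- round(mean(pix[, 1])); cc <- round(mean(pix[, 2]))
  h <- nrow(gt); w <- ncol(gt)
  cr <- clamp(cr, 1, h - 1); cc <- clamp(cc, 1, w - 1)
  quads <- list(
    list(r = 1:cr, c = 1:cc), list(r = 1:cr, c = (cc + 1):w),
    list(r = (cr + 1):h, c = 1:cc), list(r = (cr + 1):h, c = (cc + 1):w)
  )
  s_region <- 0
  for (q in quads) {
    wq <- length(q$r) * length(q$c) / (h * w)
    s_region <- s_region + wq * ssim_region(as.numeric(fm[q$r, q$c]),
                                            as.numeric(gt[q$r, q$c] * 1))
  }
  clamp(alpha * s_object + (1 - alpha) * s_region, 0, 1)
}

#' Enhanced-alignment measure (E-measure) of a saliency map
#'
#' Mean of the enhanced alignment matrix built from the mean-centred
#' agreement of prediction and truth, capturing global statistics and local
#' pixel matching jointly.
#'
#' @param pred Saliency matrix in \[0, 1\] (or a \{0, 255\} mask).
#' @param truth Truth mask over \{0, 255\} (or \{0, 1\}).
#' @return The E-measure in \[0, 1\].
#' @export
e_measure <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop_shape("pred and truth dimensions differ")
  gt <- (truth > 0.5 * max(1, max(truth))) * 1
  if (!any(gt > 0)) stop_metric("undefined metric: empty truth mask")
  fm <- if (max(pred) > 1) pred / 255 else pred
  dgt <- gt - mean(gt)
  dfm <- fm - mean(fm)
  align <- 2 * dgt * dfm / (dgt^2 + dfm^2 + .Machine$double.eps)
  enhanced <- (align + 1)^2 / 4
  clamp(mean(enhanced), 0, 1)
}

#' Measurement error metrics
#'
#' Per-sample relative error `RE_i = |S_i - Shat_i| / S_i * 100` (denominator
#' the measured value, as the device reports it; set
#' `re_denominator = "reference"` for the reference-based convention),
#' MAE, MSE, RMSE, and the coefficient of determination. As printed on the
#' device report, `R^2 = 1 - sum((Shat - S)^2) / sum((S_bar - S)^2)` with
#' `S_bar` the mean of the measured values; `r2_convention = "conventional"`
#' uses the reference mean instead.
#'
#' @param measured Numeric vector of measured diameters S_i.
#' @param reference Numeric vector of reference diameters (same length).
#' @param re_denominator `"measured"` or `"reference"`.
#' @param r2_convention `"as_printed"` or `"conventional"`.
#' @return List of class `stemspot_error_metrics` with `mae`, `mse`,
#'   `rmse`, `r_squared`, `relative_errors_pct` (NA where the denominator
#'   is 0, flagged in `re_excluded`), and `n`.
#' @export
error_metrics <- function(measured, reference,
                          re_denominator = c("measured", "reference"),
                          r2_convention = c("as_printed", "conventional")) {
  re_denominator <- match.arg(re_denominator)
  r2_convention <- match.arg(r2_convention)
  if (length(measured) != length(reference) || length(measured) < 1) {
    stop_parameter("measured and reference must have equal length >= 1")
  }
  err <- measured - reference
  denom <- if (re_denominator == "measured") measured else reference
  re <- ifelse(denom == 0, NA_real_, abs(err) / denom * 100)
  mse <- mean(err^2)
  center <- if (r2_convention == "as_printed") mean(measured) else mean(reference)
  ss_res <- sum((reference - measured)^2)
  ss_tot <- sum((center - measured)^2)
  r2 <- if (ss_res == 0) 1 else 1 - ss_res / ss_tot
  structure(list(
    mae = mean(abs(err)),
    mse = mse,
    rmse = sqrt(mse),
    r_squared = r2,
    relative_errors_pct = re,
    re_excluded = which(is.na(re)),
    n = length(measured)
  ), class = "stemspot_error_metrics")
}

#' Evaluate predicted masks against truth masks
#'
#' Convenience wrapper computing all saliency metrics per pair plus the
#' pixel-level mean absolute error, then averaging.
#'
#' @param preds,truths Lists of matrices (pairs in order).
#' @param beta_sq Beta-squared for the (weighted) F-measure.
#' @return List with the per-pair data frame (`per_sample`) and the means.
#' @export
evaluate_masks <- function(preds, truths, beta_sq = 0.3) {
  if (length(preds) != length(truths) || length(preds) == 0) {
    stop_parameter("preds and truths must be non-empty lists of equal length")
  }
  rows <- lapply(seq_along(preds), function(i) {
    p <- preds[[i]]; g <- truths[[i]]
    pm <- if (max(p) > 1) p / 255 else p
    gm <- (g > 0.5 * max(1, max(g))) * 1
    tp <- sum(pm > 0.5 & gm > 0)
    prec <- if (sum(pm > 0.5) > 0) tp / sum(pm > 0.5) else 0
    rec <- tp / sum(gm > 0)
    data.frame(
      sample = i,
      mae = mean(abs(pm - gm)),
      f_measure = if (prec + rec == 0) 0 else f_measure(prec, rec, beta_sq),
      weighted_f_measure = weighted_f_measure(p, g, beta_sq),
      s_measure = s_measure(p, g),
      e_measure = e_measure(p, g)
    )
  })
  per_sample <- do.call(rbind, rows)
  means <- colMeans(per_sample[, -1, drop = FALSE])
  list(per_sample = per_sample, means = as.list(means))
}
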