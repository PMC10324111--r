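# Internal helpers: classed conditions, image validation, resampling, gradients.

stop_stemspot <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "stemspot_error", "error", "condition")))
}

stop_parameter <- function(msg) stop_stemspot(msg, "stemspot_parameter_error")
stop_shape <- function(msg) stop_stemspot(msg, "stemspot_shape_error")
stop_no_spot <- function(msg) stop_stemspot(msg, "stemspot_no_spot_error")
stop_insufficient_edge <- function(msg) stop_stemspot(msg, "stemspot_insufficient_edge_error")
stop_no_trunk <- function(msg) stop_stemspot(msg, "stemspot_no_trunk_error")
stop_measurement <- function(msg) stop_stemspot(msg, "stemspot_measurement_error")
stop_metric <- function(msg) stop_stemspot(msg, "stemspot_metric_error")
stop_numeric <- function(msg) stop_stemspot(msg, "stemspot_numeric_error")
stop_training <- function(msg) stop_stemspot(msg, "stemspot_training_error")

assert_gray_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop_shape(sprintf("`%s` must be a numeric matrix (height x width)", arg))
  }
  if (anyNA(img) || any(!is.finite(img))) {
    stop_numeric(sprintf("`%s` contains non-finite values", arg))
  }
  if (min(img) < 0 || max(img) > 255) {
    stop_parameter(sprintf("`%s` intensities must lie in [0, 255]", arg))
  }
  invisible(img)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Bilinear interpolation weight matrix mapping a length-`n_in` axis to
# `n_out` samples (half-pixel centre convention, edges clamped).
resize_weights <- function(n_out, n_in) {
  if (n_out == n_in) return(diag(n_in))
  src <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5 # 1-based fractional index
  src <- clamp(src, 1, n_in)
  lo <- clamp(floor(src), 1, n_in)
  hi <- clamp(lo + 1, 1, n_in)
  w_hi <- src - lo
  m <- matrix(0, n_out, n_in)
  idx <- cbind(seq_len(n_out), lo)
  m[idx] <- m[idx] + (1 - w_hi)
  idx <- cbind(seq_len(n_out), hi)
  m[idx] <- m[idx] + w_hi
  m
}

# Bilinear resize of a matrix to (h, w).
resize_gray <- function(img, h, w) {
  rm_ <- resize_weights(h, nrow(img))
  cm_ <- resize_weights(w, ncol(img))
  rm_ %*% img %*% t(cm_)
}

# Vectorised bilinear sampling of `img` at fractional (row, col) positions;
# positions outside the frame are clamped to the border.
bilinear_sample <- function(img, r, c) {
  h <- nrow(img); w <- ncol(img)
  r <- clamp(r, 1, h); c <- clamp(c, 1, w)
  r0 <- clamp(floor(r), 1, h); r1 <- clamp(r0 + 1, 1, h)
  c0 <- clamp(floor(c), 1, w); c1 <- clamp(c0 + 1, 1, w)
  fr <- r - r0; fc <- c - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c1)] * (1 - fr) * fc +
    img[cbind(r1, c1)] * fr * fc
}

# Sobel gradient magnitude with replicated borders.
sobel_magnitude <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- conv3_replicate(img, kx)
  gy <- conv3_replicate(img, t(kx))
  sqrt(gx^2 + gy^2)
}

# 3x3 correlation with replicate padding (small, allocation-light).
conv3_replicate <- function(img, k) {
  h <- nrow(img); w <- ncol(img)
  p <- img[c(1, seq_len(h), h), c(1, seq_len(w), w)]
  out <- matrix(0, h, w)
  for (i in 1:3) for (j in 1:3) {
    if (k[i, j] != 0) {
      out <- out + k[i, j] * p[(i - 1) + seq_len(h), (j - 1) + seq_len(w)]
    }
  }
  out
}

# Gaussian blur via EBImage (sigma in pixels); returns plain matrix.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  as.matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma, boundary = "replicate"))
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) && x == round(x)
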