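# Image and record I/O: 8-bit grayscale PNG in, JSON/CSV out.

#' Read a grayscale image
#'
#' Reads PNG (also TIFF when the `tiff` package is available) into the
#' package's matrix convention (rows x cols, intensities 0-255). Colour
#' images are converted to luminance with a warning -- the device sensor is
#' panchromatic.
#'
#' @param path Image file.
#' @return Gray image matrix.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop_parameter(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  a <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop_parameter("reading TIFF requires the 'tiff' package")
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(a)) == 3) {
    warning("colour image converted to luminance (device is panchromatic)")
    a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  }
  a * 255
}

#' Write a grayscale image as 8-bit PNG
#'
#' @param img Gray image matrix (0-255).
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  png::writePNG(clamp(img, 0, 255) / 255, path)
  invisible(path)
}

#' Write a synthetic scene to disk
#'
#' Writes the image and mask as 8-bit grayscale PNG plus a JSON sidecar of
#' the truth record.
#'
#' @param scene A [generate_scene()] object.
#' @param dir Output directory (created if missing).
#' @param id Basename stem for the three files.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_scene <- function(scene, dir, id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    image = file.path(dir, sprintf("%s_image.png", id)),
    mask = file.path(dir, sprintf("%s_mask.png", id)),
    truth = file.path(dir, sprintf("%s_truth.json", id))
  )
  write_gray_png(scene$image, paths[["image"]])
  write_gray_png(scene$trunk_mask, paths[["mask"]])
  truth <- scene$truth
  truth$params <- unclass(truth$params)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Serialise a spot fit or measurement record to JSON
#'
#' @param x A `stemspot_spotfit` or `stemspot_measurement` object.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_record_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

measurement_to_row <- function(rec) {
  data.frame(
    image_id = rec$image_id,
    stem_diameter_cm = rec$stem_diameter_cm,
    height_cm = rec$height_cm,
    stem_width_px = rec$stem_width_px,
    spot_diameter_px = rec$spot_diameter_px,
    height_px = rec$height_px,
    scale_mm_per_px = rec$scale_mm_per_px,
    spot_row = rec$spot_centroid[1],
    spot_col = rec$spot_centroid[2],
    measurement_row = rec$measurement_row,
    segmenter = rec$segmenter,
    mode = rec$mode,
    warnings = paste(rec$warnings, collapse = "; "),
    stringsAsFactors = FALSE
  )
}
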