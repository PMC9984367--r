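#' Read a grayscale image as a height field
#'
#' Reads a PNG or TIFF micrograph and returns intensities normalized to
#' \[0, 1\] by bit depth (8-bit values divided by 255, 16-bit by 65535, as the
#' underlying readers do). RGB input is converted to luminance
#' (0.2126 R + 0.7152 G + 0.0722 B) with a warning. The pixel scale is always
#' user-supplied: vendor SEM TIFF tags are nonstandard and are not parsed.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param pixel_scale micrometres per pixel.
#' @return A [height_field()].
#' @export
read_image <- function(path, pixel_scale = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(img)) == 3) {
    nch <- dim(img)[3]
    warning("multi-channel image converted to luminance")
    img <- if (nch >= 3)
      0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    else img[, , 1]
  }
  height_field(img, pixel_scale)
}

#' Write a height field as a grayscale image
#'
#' Writes values clipped to \[0, 1\] as grayscale. TIFF honours
#' `bits_per_sample` (8 or 16); PNG is written at 8 bits. A round trip
#' through [read_image()] is lossless up to one quantization step of the
#' written bit depth.
#'
#' @param field a [height_field()] with values in \[0, 1\].
#' @param path output path (`.png`, `.tif`, `.tiff`).
#' @param bits_per_sample 8 or 16 (TIFF only).
#' @return `path`, invisibly.
#' @export
write_image <- function(field, path, bits_per_sample = 16) {
  stopifnot(is_height_field(field), bits_per_sample %in% c(8, 16))
  v <- pmin(pmax(field$values, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(v, path),
    tif = ,
    tiff = tiff::writeTIFF(v, path, bits.per.sample = bits_per_sample),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}

#' Binarize a height field
#'
#' Thresholds a grayscale field into solid phase vs background. The default
#' threshold is Otsu's criterion (maximizing between-class variance); a manual
#' threshold overrides it. By default brighter pixels map to white (solid
#' phase), matching the backscatter appearance of the starch/protein matrix in
#' endosperm micrographs; set `polarity = "dark"` to invert.
#'
#' @param field a [height_field()].
#' @param method `"otsu"` or `"manual"`.
#' @param threshold numeric threshold in the units of `field$values`;
#'   required when `method = "manual"`.
#' @param polarity `"bright"` (default: values above threshold become white)
#'   or `"dark"` (complement).
#' @return A [binary_image()] with the threshold stored as attribute
#'   `threshold`.
#' @examples
#' hf <- height_field(matrix(c(rep(0.2, 32), rep(0.8, 32)), 8, 8))
#' bi <- binarize(hf)
#' mean(bi$mask)
#' @export
binarize <- function(field, method = c("otsu", "manual"), threshold = NULL,
                     polarity = c("bright", "dark")) {
  stopifnot(is_height_field(field))
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  v <- field$values
  if (method == "manual") {
    if (is.null(threshold)) stop("`threshold` required for manual method")
    thr <- threshold
  } else {
    rng <- range(v)
    if (diff(rng) == 0)
      stop("constant image: automatic thresholding is undefined")
    thr <- EBImage::otsu(EBImage::Image(v), range = rng)
  }
  mask <- v > thr
  if (polarity == "dark") mask <- !mask
  out <- binary_image(mask, field$pixel_scale)
  attr(out, "threshold") <- as.numeric(thr)
  out
}
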