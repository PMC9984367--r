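#' Height field (grayscale image treated as a surface)
#'
#' A 2-D scalar field of surface heights in arbitrary intensity units plus the
#' physical size of one pixel. This is the substrate for all texture analysis:
#' the autocorrelation map, the structure function and the fractal fit.
#'
#' @param values numeric matrix of finite values.
#' @param pixel_scale physical size of one pixel, micrometres per pixel.
#' @return An object of class `height_field` with elements `values` and
#'   `pixel_scale`.
#' @examples
#' hf <- height_field(matrix(rnorm(64), 8, 8), pixel_scale = 0.5)
#' hf
#' @export
height_field <- function(values, pixel_scale = 1) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (any(!is.finite(values)))
    stop("`values` must be finite")
  if (!is.numeric(pixel_scale) || length(pixel_scale) != 1 || pixel_scale <= 0)
    stop("`pixel_scale` must be a single positive number")
  structure(list(values = values, pixel_scale = as.numeric(pixel_scale)),
            class = "height_field")
}

#' @export
print.height_field <- function(x, ...) {
  cat(sprintf("<height_field> %d x %d px, pixel scale %g um/px\n",
              nrow(x$values), ncol(x$values), x$pixel_scale))
  cat(sprintf("  height range [%.4g, %.4g], rms %.4g\n",
              min(x$values), max(x$values),
              sqrt(mean((x$values - mean(x$values))^2))))
  invisible(x)
}

#' Binary image (segmented solid phase)
#'
#' Logical mask in which `TRUE` ("white") marks the solid phase -- in endosperm
#' micrographs the starch + protein matrix -- and `FALSE` ("black") the voids.
#'
#' @param mask logical matrix with at least one pixel.
#' @param pixel_scale micrometres per pixel.
#' @return An object of class `binary_image` with elements `mask` and
#'   `pixel_scale`.
#' @examples
#' bi <- binary_image(matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2), 0.5)
#' bi
#' @export
binary_image <- function(mask, pixel_scale = 1) {
  if (is.numeric(mask)) mask <- mask > 0
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix")
  if (length(mask) == 0) stop("`mask` must contain at least one pixel")
  if (any(is.na(mask))) stop("`mask` must not contain NA")
  if (!is.numeric(pixel_scale) || length(pixel_scale) != 1 || pixel_scale <= 0)
    stop("`pixel_scale` must be a single positive number")
  structure(list(mask = mask, pixel_scale = as.numeric(pixel_scale)),
            class = "binary_image")
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("<binary_image> %d x %d px, pixel scale %g um/px, %.1f%% white\n",
              nrow(x$mask), ncol(x$mask), x$pixel_scale,
              100 * mean(x$mask)))
  invisible(x)
}

is_height_field <- function(x) inherits(x, "height_field")
is_binary_image <- function(x) inherits(x, "binary_image")

as_height_field <- function(x, pixel_scale = 1) {
  if (is_height_field(x)) return(x)
  height_field(as.matrix(x), pixel_scale)
}

# Run `expr` under a private RNG stream, restoring the caller's stream after.
# Generators take explicit seeds and must not disturb global reproducibility.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
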