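#' Connected-component labeling
#'
#' Labels connected foreground regions of a logical mask. White (foreground)
#' components conventionally use 8-connectivity and black (background)
#' components 4-connectivity -- the complementary pair that avoids
#' connectivity paradoxes on the digital plane.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of labels (background 0), labels assigned in
#'   raster-scan order.
#' @export
label_components <- function(mask, connectivity = 8) {
  if (is_binary_image(mask)) mask <- mask$mask
  stopifnot(is.matrix(mask), is.logical(mask))
  .label_components_cpp(mask, as.integer(connectivity))
}

#' Watershed segmentation of touching granules
#'
#' Splits touching convex particles in a binary image at their necks by
#' running the watershed transform on the Euclidean distance map of the mask
#' (seeds are distance-map maxima, so each particle core becomes one catchment
#' basin). Standard practice for separating contacting starch granules in
#' micrographs.
#'
#' @param binary a [binary_image()].
#' @param min_distance_px minimum separation (in pixels) between distance-map
#'   peaks treated as distinct seeds; larger values merge over-segmented
#'   fragments. Default 3.
#' @param tolerance minimum height difference between a peak and its
#'   neighbourhood for it to seed an object (watershed `tolerance`).
#' @return Integer label matrix: 0 background, each granule a positive label.
#'   Every white pixel carries exactly one label.
#' @examples
#' pk <- granule_packing(c(A = 0, B = 2, C = 5), size_px = 128,
#'                       pixel_scale = 0.5, seed = 2)
#' lab <- watershed_segment(pk$image)
#' max(lab)  # number of granules found
#' @export
watershed_segment <- function(binary, min_distance_px = 3, tolerance = 1) {
  stopifnot(is_binary_image(binary))
  if (!any(binary$mask)) {
    warning("empty mask: returning empty labeling")
    return(matrix(0L, nrow(binary$mask), ncol(binary$mask)))
  }
  dm <- EBImage::distmap(EBImage::Image(binary$mask * 1))
  lab <- EBImage::watershed(dm, tolerance = tolerance, ext = min_distance_px)
  m <- EBImage::imageData(lab)
  storage.mode(m) <- "integer"
  m
}

#' Measure segmented granules
#'
#' Converts a label image into per-granule physical measurements: area in
#' square micrometres (pixel count times pixel scale squared), centroid and
#' equivalent circular diameter.
#'
#' @param labeled integer label matrix from [watershed_segment()].
#' @param pixel_scale micrometres per pixel.
#' @return A `granule_set`: data frame with `label`, `area_um2`,
#'   `equiv_diameter_um`, `centroid_row`, `centroid_col`, and attribute
#'   `image_area_um2`.
#' @export
measure_granules <- function(labeled, pixel_scale) {
  stopifnot(is.matrix(labeled))
  if (!is.numeric(pixel_scale) || length(pixel_scale) != 1 || pixel_scale <= 0)
    stop("`pixel_scale` must be a single positive number")
  labs <- labeled[labeled > 0]
  if (length(labs) == 0) {
    out <- data.frame(label = integer(), area_um2 = numeric(),
                      equiv_diameter_um = numeric(),
                      centroid_row = numeric(), centroid_col = numeric())
  } else {
    ids <- sort(unique(labs))
    npix <- tabulate(labs, nbins = max(ids))[ids]
    rows <- row(labeled)[labeled > 0]
    cols <- col(labeled)[labeled > 0]
    cr <- vapply(split(rows, labeled[labeled > 0]), mean, numeric(1))
    cc <- vapply(split(cols, labeled[labeled > 0]), mean, numeric(1))
    area <- npix * pixel_scale^2
    out <- data.frame(label = ids, area_um2 = area,
                      equiv_diameter_um = 2 * sqrt(area / pi),
                      centroid_row = as.numeric(cr[as.character(ids)]),
                      centroid_col = as.numeric(cc[as.character(ids)]))
  }
  attr(out, "image_area_um2") <- length(labeled) * pixel_scale^2
  class(out) <- c("granule_set", class(out))
  out
}

#' Classify granules into A/B/C size types
#'
#' Starch granules are typed by cross-sectional area: type A above 177 um^2
#' (circle diameter > 15 um), type C below 20 um^2 (diameter < 5 um), type B
#' in the closed band \[20, 177\] um^2 (5--15 um). The thresholds are the
#' circle areas at the 15 um and 5 um diameter cutoffs rounded to integers.
#'
#' @param granules a `granule_set` from [measure_granules()], or a numeric
#'   vector of areas in um^2.
#' @return The granule set with a `type` factor column and attribute
#'   `type_summary` (counts and percentages per type, percentages summing to
#'   100); for a numeric vector, the factor of types.
#' @examples
#' classify_granules(c(510.4, 100, 10))
#' @export
classify_granules <- function(granules) {
  cuts <- granule_area_cutoffs()
  type_of <- function(a)
    factor(ifelse(a > cuts["A_min"], "A", ifelse(a < cuts["C_max"], "C", "B")),
           levels = c("A", "B", "C"))
  if (is.numeric(granules)) return(type_of(granules))
  stopifnot(inherits(granules, "granule_set"))
  granules$type <- type_of(granules$area_um2)
  counts <- table(granules$type)
  pct <- if (sum(counts) > 0) 100 * as.numeric(counts) / sum(counts)
         else rep(NA_real_, 3)
  attr(granules, "type_summary") <- data.frame(
    type = c("A", "B", "C"), count = as.integer(counts), percent = pct)
  granules
}

#' Granule type area cutoffs
#'
#' Circle areas at the class-boundary diameters 15 um and 5 um, rounded to
#' integers: 177 um^2 (A/B boundary) and 20 um^2 (B/C boundary).
#'
#' @param round_to_integer round the circle areas (default, the convention
#'   used in endosperm work) or return them exact.
#' @return Named vector `c(A_min = 177, C_max = 20)` (or unrounded).
#' @export
granule_area_cutoffs <- function(round_to_integer = TRUE) {
  x <- c(A_min = pi * 7.5^2, C_max = pi * 2.5^2)
  if (round_to_integer) round(x) else x
}

#' Minkowski functionals of a binary image
#'
#' Computes the three additive morphological measures of a two-phase image:
#' the solid-phase share `V = N_w / N * 100%`, the interphase boundary share
#' `S = N_bound / N * 100%`, and the Euler-Poincare characteristic
#' `chi = (C_w - C_b) / N`, where `N` is the pixel count, `N_w` the white
#' pixel count, `N_bound` the number of unordered 4-adjacent white--black
#' pixel pairs, and `C_w`, `C_b` the numbers of white (8-connected) and black
#' (4-connected) areas. All counts are exact integers before division.
#' On adversarial inputs (e.g. a checkerboard) `S` can exceed 100%; it is
#' reported unclamped.
#'
#' @param binary a [binary_image()].
#' @return Object of class `minkowski_summary`: list with `V`, `void_share`
#'   (`= 100 - V` exactly), `S`, `chi`, `chi_e3` (`chi * 1e3`, the display
#'   convention), and the raw counts `N`, `N_w`, `N_bound`, `C_w`, `C_b`.
#' @examples
#' m <- matrix(FALSE, 2, 2); m[1, 1] <- TRUE
#' minkowski_functionals(binary_image(m))
#' @export
minkowski_functionals <- function(binary) {
  stopifnot(is_binary_image(binary))
  mask <- binary$mask
  N <- length(mask)
  N_w <- sum(mask)
  N_bound <- .count_phase_boundaries_cpp(mask)
  C_w <- max(0L, max(.label_components_cpp(mask, 8L)))
  C_b <- max(0L, max(.label_components_cpp(!mask, 4L)))
  V <- 100 * N_w / N
  structure(list(V = V, void_share = 100 - V,
                 S = 100 * N_bound / N,
                 chi = (C_w - C_b) / N,
                 chi_e3 = 1e3 * (C_w - C_b) / N,
                 N = N, N_w = N_w, N_bound = N_bound,
                 C_w = C_w, C_b = C_b),
            class = "minkowski_summary")
}

#' @export
print.minkowski_summary <- function(x, ...) {
  cat("Minkowski functionals\n")
  cat(sprintf("  solid phase V        %8.3f %%\n", x$V))
  cat(sprintf("  void share           %8.3f %%\n", x$void_share))
  cat(sprintf("  boundary share S     %8.3f %%\n", x$S))
  cat(sprintf("  Euler-Poincare chi   %8.3f x 10^-3  (C_w=%d, C_b=%d)\n",
              x$chi_e3, x$C_w, x$C_b))
  invisible(x)
}

#' Granule coverage rate
#'
#' Number of granules per square micrometre of analysed surface.
#'
#' @param granules a `granule_set` (its `image_area_um2` attribute supplies
#'   the denominator) or an integer count.
#' @param image_area_um2 analysed area, required when `granules` is a count.
#' @return Coverage rate in granules per um^2 (>= 0).
#' @examples
#' coverage_rate(50, image_area_um2 = 1000)  # 0.05
#' @export
coverage_rate <- function(granules, image_area_um2 = NULL) {
  if (inherits(granules, "granule_set")) {
    n <- nrow(granules)
    if (is.null(image_area_um2))
      image_area_um2 <- attr(granules, "image_area_um2")
  } else {
    n <- as.numeric(granules)
  }
  if (is.null(image_area_um2) || image_area_um2 <= 0)
    stop("`image_area_um2` must be positive")
  n / image_area_um2
}

#' Full endosperm morphology summary for one binary micrograph
#'
#' Convenience wrapper chaining [watershed_segment()], [measure_granules()],
#' [classify_granules()], [minkowski_functionals()] and [coverage_rate()] into
#' the per-image summary used for cultivar comparison (solid/void/boundary
#' shares, Euler-Poincare characteristic, granule area statistics, type
#' percentages, coverage rate).
#'
#' @param binary a [binary_image()].
#' @param min_distance_px passed to [watershed_segment()].
#' @return List of class `endosperm_summary` with `minkowski`, `granules`,
#'   `type_summary`, `coverage_rate_um2`, and area statistics.
#' @export
endosperm_morphology <- function(binary, min_distance_px = 3) {
  lab <- watershed_segment(binary, min_distance_px)
  gr <- classify_granules(measure_granules(lab, binary$pixel_scale))
  mk <- minkowski_functionals(binary)
  structure(list(
    minkowski = mk,
    granules = gr,
    type_summary = attr(gr, "type_summary"),
    coverage_rate_um2 = coverage_rate(gr),
    area_mean_um2 = if (nrow(gr)) mean(gr$area_um2) else NA_real_,
    area_sd_um2 = if (nrow(gr) > 1) sd(gr$area_um2) else NA_real_,
    area_min_um2 = if (nrow(gr)) min(gr$area_um2) else NA_real_,
    area_max_um2 = if (nrow(gr)) max(gr$area_um2) else NA_real_
  ), class = "endosperm_summary")
}

#' @export
print.endosperm_summary <- function(x, ...) {
  cat(sprintf("Endosperm morphology: %d granules, coverage %.4f um^-2\n",
              nrow(x$granules), x$coverage_rate_um2))
  cat(sprintf("  granule area mean %.3f um^2 (min %.3f, max %.3f)\n",
              x$area_mean_um2, x$area_min_um2, x$area_max_um2))
  ts <- x$type_summary
  cat(sprintf("  type %s: %d (%.2f%%)\n", ts$type, ts$count, ts$percent),
      sep = "")
  print(x$minkowski)
  invisible(x)
}
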