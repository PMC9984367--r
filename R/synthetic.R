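#' Synthesize a self-affine (fractional Brownian) surface
#'
#' Spectral synthesis of an isotropic self-affine Gaussian surface with Hurst
#' exponent `hurst`. A real white-noise field is filtered in the Fourier domain
#' with amplitude proportional to `f^-(hurst + 1)` (power spectral density
#' `f^-(2 hurst + 2)`, the 2-D fractional-Brownian scaling), so the structure
#' function scales as `S(tau) ~ tau^(2 hurst)` over the self-affine regime and
#' the surface fractal dimension is `D = 3 - hurst`. No window is applied at
#' generation so the prescribed spectrum is exact; windowing is an analysis
#' choice (see [autocorrelation()]).
#'
#' @param size_px side of the square field in pixels (>= 64).
#' @param hurst Hurst exponent, strictly inside (0, 1). Larger values give
#'   smoother surfaces (smaller fractal dimension).
#' @param pixel_scale micrometres per pixel.
#' @param seed integer seed; the generator is a pure function of its arguments.
#' @param rms target root-mean-square height of the output (default 1).
#' @return A [height_field()] with attribute `ground_truth` listing
#'   `hurst` and the implied surface dimension `D_true = 3 - hurst`.
#' @examples
#' hf <- fbm_surface(128, hurst = 0.5, seed = 1)
#' attr(hf, "ground_truth")$D_true
#' @seealso [fit_fractal()] which recovers `D` from the structure function.
#' @export
fbm_surface <- function(size_px, hurst, pixel_scale = 1, seed = NULL, rms = 1) {
  if (!is.numeric(size_px) || size_px < 64)
    stop("`size_px` must be >= 64")
  if (!is.numeric(hurst) || hurst <= 0 || hurst >= 1)
    stop("`hurst` must lie strictly inside (0, 1)")
  n <- as.integer(size_px)
  z <- with_seed(seed, {
    w <- matrix(rnorm(n * n), n, n)
    f1 <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
    fr <- sqrt(outer(f1^2, f1^2, "+"))
    amp <- fr^(-(hurst + 1))
    amp[1, 1] <- 0                      # zero-mean field
    zf <- fft(w) * amp
    Re(fft(zf, inverse = TRUE)) / (n * n)
  })
  z <- z - mean(z)
  z <- z * (rms / sqrt(mean(z^2)))
  out <- height_field(z, pixel_scale)
  attr(out, "ground_truth") <- list(hurst = hurst, D_true = 3 - hurst)
  out
}

#' Synthesize an anisotropic Gaussian random field
#'
#' Stationary Gaussian field with separable squared-exponential covariance
#' `R(dx, dy) = exp(-(dx/lx)^2 - (dy/ly)^2)` (lags in pixels along matrix rows
#' and columns). The autocorrelation decay length along each axis is
#' proportional to the corresponding correlation length, so the ground-truth
#' surface anisotropy ratio is `Str_true = min(lx, ly) / max(lx, ly)`.
#'
#' @param size_px side of the square field in pixels (>= 64).
#' @param lengths positive pair `c(lx, ly)`: correlation lengths in pixels
#'   along the two image axes.
#' @inheritParams fbm_surface
#' @return A [height_field()] with attribute `ground_truth` carrying `lengths`
#'   and `Str_true`.
#' @examples
#' hf <- anisotropic_field(128, c(4, 16), seed = 1)
#' attr(hf, "ground_truth")$Str_true
#' @export
anisotropic_field <- function(size_px, lengths, pixel_scale = 1, seed = NULL,
                              rms = 1) {
  if (!is.numeric(size_px) || size_px < 64)
    stop("`size_px` must be >= 64")
  if (length(lengths) != 2 || any(!is.finite(lengths)) || any(lengths <= 0))
    stop("`lengths` must be two positive correlation lengths")
  n <- as.integer(size_px)
  lx <- lengths[1]; ly <- lengths[2]
  z <- with_seed(seed, {
    w <- matrix(rnorm(n * n), n, n)
    f1 <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
    # target ACF exp(-(d/l)^2) per axis has PSD ~ exp(-(pi l f)^2);
    # the filter is the square root of the PSD
    ax <- exp(-(pi * lx * f1)^2 / 2)
    ay <- exp(-(pi * ly * f1)^2 / 2)
    amp <- outer(ax, ay)
    amp[1, 1] <- 0
    zf <- fft(w) * amp
    Re(fft(zf, inverse = TRUE)) / (n * n)
  })
  z <- z - mean(z)
  z <- z * (rms / sqrt(mean(z^2)))
  out <- height_field(z, pixel_scale)
  attr(out, "ground_truth") <- list(lengths = c(lx, ly),
                                    Str_true = min(lx, ly) / max(lx, ly))
  out
}

# A/B/C granule size classes, radii in micrometres. The class bands are the
# circle areas at diameters 5 and 15 um (20 and 177 um^2 after rounding).
granule_radius_bands <- function() {
  list(A = c(7.5, 12), B = c(2.5, 7.5), C = c(0.8, 2.5))
}

#' Generate a synthetic starch-granule packing with exact ground truth
#'
#' Places non-overlapping discs of the three granule size classes (A: diameter
#' > 15 um, B: 5--15 um, C: < 5 um) into a square image by rejection sampling.
#' Disc boundaries are kept at least 2 px apart so segmentation can never merge
#' neighbours, and radii are sampled at least 1 px inside the class band so
#' pixel discretization cannot flip a class label. The returned ground truth
#' (centres, radii, types) is exact by construction.
#'
#' @param counts named integer vector `c(A = ..., B = ..., C = ...)` of discs
#'   per class; at least one must be positive.
#' @param size_px side of the square image in pixels.
#' @param pixel_scale micrometres per pixel.
#' @param seed integer seed.
#' @param target_solid_fraction optional target white-pixel fraction in (0, 1);
#'   purely diagnostic: a warning reports a shortfall beyond +/- 0.05.
#' @param max_attempts rejection-sampling attempts per disc before declaring
#'   the packing infeasible.
#' @return A list with `image` (a [binary_image()]) and `granules` (data frame
#'   of `id`, `type`, `x_px`, `y_px`, `radius_um`, `area_um2` -- the exact
#'   ground truth), plus `solid_fraction` realized.
#' @examples
#' pk <- granule_packing(c(A = 1, B = 4, C = 10), size_px = 256,
#'                       pixel_scale = 0.5, seed = 1)
#' table(pk$granules$type)
#' @export
granule_packing <- function(counts, size_px = 512, pixel_scale = 0.5,
                            seed = NULL, target_solid_fraction = NULL,
                            max_attempts = 5000) {
  counts <- unlist(counts)
  if (is.null(names(counts))) {
    if (length(counts) != 3)
      stop("unnamed `counts` must have length 3 (A, B, C)")
  } else {
    counts <- counts[c("A", "B", "C")]
  }
  names(counts) <- c("A", "B", "C")
  counts[is.na(counts)] <- 0
  if (any(counts < 0) || sum(counts) == 0)
    stop("`counts` must be non-negative with at least one positive entry")
  n <- as.integer(size_px)
  bands <- granule_radius_bands()

  gran <- with_seed(seed, {
    rows <- list()
    id <- 0L
    # place large discs first: improves feasibility of dense requests
    for (type in c("A", "B", "C")) {
      band <- bands[[type]]
      lo <- band[1] + pixel_scale          # 1 px inside the class band
      hi <- band[2] - if (type == "A") 0 else pixel_scale
      lo <- max(lo, 2 * pixel_scale)       # >= 2 px radius: survives watershed
      if (lo >= hi)
        stop(sprintf("pixel scale %g um/px too coarse for type %s granules",
                     pixel_scale, type))
      for (k in seq_len(counts[[type]])) {
        placed <- FALSE
        for (a in seq_len(max_attempts)) {
          r_um <- runif(1, lo, hi)
          r_px <- r_um / pixel_scale
          cx <- runif(1, r_px + 1, n - r_px)   # keep discs off the border
          cy <- runif(1, r_px + 1, n - r_px)
          ok <- TRUE
          for (g in rows) {
            if ((cx - g$x_px)^2 + (cy - g$y_px)^2 <
                (r_px + g$radius_um / pixel_scale + 2)^2) { ok <- FALSE; break }
          }
          if (ok) {
            id <- id + 1L
            rows[[id]] <- list(id = id, type = type, x_px = cx, y_px = cy,
                               radius_um = r_um)
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop(sprintf(
            "packing infeasible: placed %d of %d discs (failed on type %s #%d)",
            id, sum(counts), type, k))
      }
    }
    do.call(rbind, lapply(rows, as.data.frame))
  })
  gran$area_um2 <- pi * gran$radius_um^2

  mask <- matrix(FALSE, n, n)
  xs <- matrix(seq_len(n), n, n)
  ys <- matrix(seq_len(n), n, n, byrow = TRUE)
  for (i in seq_len(nrow(gran))) {
    r_px <- gran$radius_um[i] / pixel_scale
    mask <- mask | ((xs - gran$x_px[i])^2 + (ys - gran$y_px[i])^2 <= r_px^2)
  }
  sf <- mean(mask)
  if (!is.null(target_solid_fraction) &&
      abs(sf - target_solid_fraction) > 0.05)
    warning(sprintf(
      "realized solid fraction %.3f misses target %.3f by more than 0.05",
      sf, target_solid_fraction))

  list(image = binary_image(mask, pixel_scale),
       granules = gran,
       solid_fraction = sf)
}

#' Generate a filled elliptical kernel silhouette
#'
#' Rasterizes a filled axis-aligned ellipse with axes `length_mm` x `width_mm`,
#' the idealized projection of a cereal kernel. The analytic area
#' `pi L W / 4` and the Ramanujan perimeter approximation are stored as ground
#' truth for validating silhouette measurement.
#'
#' @param length_mm,width_mm ellipse axes in millimetres (positive).
#' @param pixel_scale_mm millimetres per pixel.
#' @param margin_px background margin around the ellipse.
#' @return A [binary_image()] (pixel scale stored in mm/px) with attribute
#'   `ground_truth` = list(`area_mm2`, `perimeter_mm`, `L_mm`, `W_mm`).
#' @examples
#' sil <- kernel_silhouette(8, 4, pixel_scale_mm = 0.02)
#' attr(sil, "ground_truth")$area_mm2  # pi * 8 * 4 / 4
#' @export
kernel_silhouette <- function(length_mm, width_mm, pixel_scale_mm = 0.01,
                              margin_px = 4) {
  if (length_mm <= 0 || width_mm <= 0)
    stop("ellipse axes must be positive")
  a <- length_mm / 2; b <- width_mm / 2
  a_px <- a / pixel_scale_mm; b_px <- b / pixel_scale_mm
  nr <- ceiling(2 * a_px) + 2 * margin_px
  nc <- ceiling(2 * b_px) + 2 * margin_px
  cx <- (nr + 1) / 2; cy <- (nc + 1) / 2
  xs <- matrix(seq_len(nr), nr, nc)
  ys <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  mask <- ((xs - cx) / a_px)^2 + ((ys - cy) / b_px)^2 <= 1
  h <- ((a - b) / (a + b))^2
  per <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))  # Ramanujan
  out <- binary_image(mask, pixel_scale_mm)
  attr(out, "ground_truth") <- list(area_mm2 = pi * a * b,
                                    perimeter_mm = per,
                                    L_mm = length_mm, W_mm = width_mm)
  out
}

#' Generate a lognormal-mixture particle-size histogram
#'
#' Builds a volume-fraction histogram over log-spaced size bins from a mixture
#' of lognormal modes, the shape laser diffraction reports for flour. Soft
#' wheat flours are bimodal (a fine-particle mode near 25 um and a coarse mode
#' near 130 um); hard flours are unimodal. The analytic mixture percentiles
#' d(0.1), d(0.5), d(0.9) are stored as ground truth.
#'
#' @param modes list of `c(median, gsd, weight)` triplets: mode median (um),
#'   geometric standard deviation (> 1), and volume weight. Weights must sum
#'   to 1 (tolerance 1e-6).
#' @param n_bins number of log-spaced bins.
#' @param range_um optional size range; default spans the 1e-4 and 1 - 1e-4
#'   quantiles of the mixture.
#' @return A data frame with `size_um` (geometric bin centres) and
#'   `volume_fraction` (sums to 1), with attributes `ground_truth`
#'   (analytic d10/d50/d90 and SPAN) and `bin_edges_um`.
#' @examples
#' psd <- psd_mixture(list(c(25, 1.6, 0.45), c(130, 1.4, 0.55)))
#' attr(psd, "ground_truth")
#' @export
psd_mixture <- function(modes, n_bins = 100, range_um = NULL) {
  if (!length(modes)) stop("at least one mode required")
  m <- do.call(rbind, lapply(modes, function(x) {
    if (length(x) != 3) stop("each mode is c(median, gsd, weight)")
    x
  }))
  med <- m[, 1]; gsd <- m[, 2]; w <- m[, 3]
  if (any(med <= 0) || any(gsd <= 1)) stop("need median > 0 and gsd > 1")
  if (abs(sum(w) - 1) > 1e-6) stop("mode weights must sum to 1")
  mu <- log(med); sig <- log(gsd)
  pmix <- function(q) vapply(q, function(qi) sum(w * plnorm(qi, mu, sig)),
                             numeric(1))
  qmix <- function(p) vapply(p, function(pi) {
    lo <- min(qlnorm(pi, mu, sig)); hi <- max(qlnorm(pi, mu, sig))
    if (lo == hi) return(lo)
    uniroot(function(x) pmix(x) - pi, c(lo * 0.999, hi * 1.001))$root
  }, numeric(1))
  if (is.null(range_um)) range_um <- qmix(c(1e-4, 1 - 1e-4))
  edges <- exp(seq(log(range_um[1]), log(range_um[2]), length.out = n_bins + 1))
  frac <- diff(pmix(edges))
  frac <- frac / sum(frac)
  out <- data.frame(size_um = sqrt(edges[-1] * edges[-(n_bins + 1)]),
                    volume_fraction = frac)
  q <- qmix(c(0.1, 0.5, 0.9))
  attr(out, "ground_truth") <- list(d10 = q[1], d50 = q[2], d90 = q[3],
                                    span = (q[3] - q[1]) / q[2])
  attr(out, "bin_edges_um") <- edges
  out
}
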