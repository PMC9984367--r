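#' Geometric mean diameter of a kernel
#'
#' `Dm = (L W T)^(1/3)`: the cube root of the product of kernel length,
#' width and thickness, in millimetres.
#'
#' @param L,W,T kernel length, width, thickness (mm), positive; vectorized.
#' @return Mean diameter (mm).
#' @examples
#' mean_diameter(6.42, 2.86, 2.61)  # 3.63
#' @export
mean_diameter <- function(L, W, T) {
  if (any(L <= 0) || any(W <= 0) || any(T <= 0))
    stop("kernel dimensions must be positive")
  (L * W * T)^(1 / 3)
}

#' Thinness ratio of a kernel projection
#'
#' `Rs = P^2 / (4 pi A)`: the isoperimetric quotient of the furrow-down
#' projection. Equals 1 for a circle and grows with elongation.
#'
#' @param P projection perimeter (mm), positive; vectorized.
#' @param A projection area (mm^2), positive.
#' @return Dimensionless thinness ratio (>= 1 for consistent measurements).
#' @examples
#' thinness_ratio(20.46, 20.48)  # 1.63
#' @export
thinness_ratio <- function(P, A) {
  if (any(P <= 0) || any(A <= 0)) stop("perimeter and area must be positive")
  rs <- P^2 / (4 * pi * A)
  if (any(rs < 1 - 1e-9))
    stop("P^2 < 4 pi A violates the isoperimetric inequality: ",
         "inconsistent perimeter/area measurements")
  rs
}

#' Circularity factor of a kernel projection
#'
#' `Rc = 2 sqrt(pi A) / P`, in (0, 1]; 1 for a circle. Note the algebraic
#' identity `Rs * Rc^2 = 1`.
#'
#' @inheritParams thinness_ratio
#' @return Dimensionless circularity in (0, 1].
#' @examples
#' circularity(20.46, 20.48)  # 0.78
#' @export
circularity <- function(P, A) {
  if (any(P <= 0) || any(A <= 0)) stop("perimeter and area must be positive")
  2 * sqrt(pi * A) / P
}

#' Kernel shape descriptors from tabulated dimensions
#'
#' Computes the three shape descriptors (mean diameter, thinness ratio,
#' circularity) for a table of per-kernel measurements. Descriptors computed
#' from cultivar-mean dimensions approximate, but do not equal, means of
#' per-kernel descriptors.
#'
#' @param data data frame with columns `L`, `W`, `T` (mm) and `P_b`, `A_b`
#'   (projection-b perimeter mm / area mm^2).
#' @return `data` with columns `Dm`, `Rs`, `Rc` appended.
#' @export
shape_descriptors <- function(data) {
  need <- c("L", "W", "T", "P_b", "A_b")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  data$Dm <- mean_diameter(data$L, data$W, data$T)
  data$Rs <- thinness_ratio(data$P_b, data$A_b)
  data$Rc <- circularity(data$P_b, data$A_b)
  data
}

# Moore-neighbour (8-connected) contour tracing. Returns the Freeman chain of
# boundary moves of the single foreground region.
trace_contour <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  # start: first foreground pixel in raster order
  idx <- which(mask)
  start <- c((idx[1] - 1) %% nr + 1, (idx[1] - 1) %/% nr + 1)
  # neighbour order: clockwise starting east
  dr <- c(0, 1, 1, 1, 0, -1, -1, -1)
  dc <- c(1, 1, 0, -1, -1, -1, 0, 1)
  inside <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c]
  cur <- start
  dir <- 7L  # backtrack direction: pretend we entered moving east
  moves <- integer(0)
  repeat {
    found <- FALSE
    for (k in 0:7) {
      d <- (dir + k) %% 8
      r2 <- cur[1] + dr[d + 1]; c2 <- cur[2] + dc[d + 1]
      if (inside(r2, c2)) {
        moves <- c(moves, d)
        cur <- c(r2, c2)
        dir <- (d + 6) %% 8  # next search starts from the backtrack direction
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    if (all(cur == start) && length(moves) > 2) break
    if (length(moves) > 8 * (nr * nc)) stop("contour tracing failed")
  }
  moves
}

#' Measure a single kernel silhouette
#'
#' Measures area, perimeter and the best-fit-ellipse axes of a single
#' connected silhouette, the image-analysis route to the shape descriptors.
#' Area is the pixel count times the squared pixel scale. The perimeter uses
#' Moore-neighbour contour tracing with the Kulpa step weights (0.948 per
#' axial move, 1.340 per diagonal move), which corrects the ~11% overestimate
#' of naive pixel-edge counting on smooth outlines. Length and width are the
#' major/minor axes of the ellipse with the region's second moments.
#'
#' @param binary a [binary_image()] containing exactly one connected
#'   (8-connectivity) region of at least 9 pixels; the pixel scale is
#'   interpreted in the length unit of interest (mm/px for kernels).
#' @return List with `A` (area), `P` (perimeter), `L`, `W` (axis lengths),
#'   in the pixel-scale unit, plus `Rs` and `Rc` computed from `A` and `P`.
#' @examples
#' sil <- kernel_silhouette(4, 2, pixel_scale_mm = 0.02)
#' silhouette_measure(sil)$L  # ~4 mm
#' @export
silhouette_measure <- function(binary) {
  stopifnot(is_binary_image(binary))
  mask <- binary$mask
  lab <- .label_components_cpp(mask, 8L)
  ncomp <- max(lab)
  if (ncomp != 1)
    stop(sprintf("expected one connected silhouette, found %d components",
                 ncomp))
  if (sum(mask) < 9) stop("silhouette too small (fewer than 9 pixels)")
  s <- binary$pixel_scale
  A <- sum(mask) * s^2
  moves <- trace_contour(mask)
  n_diag <- sum(moves %% 2 == 1)
  n_axial <- length(moves) - n_diag
  P <- (0.948 * n_axial + 1.340 * n_diag) * s
  rs <- row(mask)[mask]; cs <- col(mask)[mask]
  cov <- stats::cov(cbind(rs, cs)) * (length(rs) - 1) / length(rs) +
    diag(2) / 12  # per-pixel second moment
  ev <- eigen(cov, symmetric = TRUE)$values
  L <- 4 * sqrt(ev[1]) * s
  W <- 4 * sqrt(ev[2]) * s
  # computed directly: perimeter discretization can leave Rs marginally
  # below 1 for a near-circular silhouette, which is not a measurement error
  list(A = A, P = P, L = L, W = W,
       Rs = P^2 / (4 * pi * A), Rc = 2 * sqrt(pi * A) / P)
}
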