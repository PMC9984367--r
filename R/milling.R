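#' Specific milling energy
#'
#' `E_r = (E_c - E_s) / m_g`: net milling energy per unit grain mass, where
#' `E_c` is the total energy consumed by the mill, `E_s` the idle energy
#' (idle power times milling time) and `m_g` the milled grain mass.
#'
#' @param E_c total energy consumed (kJ); vectorized.
#' @param m_g grain mass (kg), positive.
#' @param E_s idle energy (kJ); alternatively supply `idle_power_kW` and
#'   `time_s`.
#' @param idle_power_kW,time_s idle power draw (kW) and milling time (s),
#'   used to compute `E_s = idle_power_kW * time_s` when `E_s` is missing.
#' @return Specific milling energy (kJ/kg), non-negative.
#' @examples
#' specific_milling_energy(E_c = 10.125, E_s = 1.0, m_g = 0.125)  # 73
#' @export
specific_milling_energy <- function(E_c, m_g, E_s = NULL,
                                    idle_power_kW = NULL, time_s = NULL) {
  if (is.null(E_s)) {
    if (is.null(idle_power_kW) || is.null(time_s))
      stop("supply `E_s` or both `idle_power_kW` and `time_s`")
    E_s <- idle_power_kW * time_s
  }
  if (any(m_g <= 0)) stop("grain mass must be positive")
  if (any(E_s < 0)) stop("idle energy must be non-negative")
  if (any(E_c < E_s))
    stop("total energy below idle energy: inconsistent milling record")
  (E_c - E_s) / m_g
}

#' Particle-size distribution summary
#'
#' Summarizes a laser-diffraction volume-fraction histogram: the percentiles
#' d(0.1), d(0.5), d(0.9) (sizes below which 10/50/90% of the particle volume
#' lies), the volume-weighted mean size `d_avg = sum(phi_i d_i)`, and the
#' relative distribution width `SPAN = (d(0.9) - d(0.1)) / d(0.5)`.
#' Percentiles are obtained by linear interpolation of the cumulative volume
#' curve against log size (the laser-diffraction convention; set
#' `log_axis = FALSE` for a linear size axis). The cumulative value assigned
#' to each bin centre is the midpoint estimate (cumulative fraction below the
#' bin plus half the bin's own fraction).
#'
#' @param size_um bin centre sizes (um). Unsorted input is sorted with a
#'   warning.
#' @param volume_fraction non-negative fractions; must sum to 1 within 1e-6
#'   (renormalized) and not be all zero.
#' @param log_axis interpolate percentiles on log size (default) or linear.
#' @return Object of class `psd_summary`: list with `d10`, `d50`, `d90`,
#'   `d_avg` (um) and `span`. A single-bin (or zero-width) distribution gives
#'   `span = 0` with a warning.
#' @examples
#' psd <- psd_mixture(list(c(25, 1.6, 0.45), c(130, 1.4, 0.55)))
#' psd_summary(psd$size_um, psd$volume_fraction)
#' @export
psd_summary <- function(size_um, volume_fraction, log_axis = TRUE) {
  if (length(size_um) != length(volume_fraction))
    stop("`size_um` and `volume_fraction` lengths differ")
  if (any(volume_fraction < 0)) stop("volume fractions must be non-negative")
  tot <- sum(volume_fraction)
  if (tot == 0) stop("all volume fractions are zero")
  if (abs(tot - 1) > 1e-6)
    stop("volume fractions must sum to 1 (within 1e-6); got ", format(tot))
  volume_fraction <- volume_fraction / tot
  if (is.unsorted(size_um)) {
    warning("sizes not sorted; sorting")
    o <- order(size_um)
    size_um <- size_um[o]; volume_fraction <- volume_fraction[o]
  }
  d_avg <- sum(size_um * volume_fraction)
  cum <- cumsum(volume_fraction) - volume_fraction / 2
  x <- if (log_axis) log(size_um) else size_um
  pick <- function(q) {
    if (q <= cum[1]) return(size_um[1])
    if (q >= cum[length(cum)]) return(size_um[length(cum)])
    i <- max(which(cum <= q))
    xi <- x[i] + (q - cum[i]) / (cum[i + 1] - cum[i]) * (x[i + 1] - x[i])
    if (log_axis) exp(xi) else xi
  }
  d10 <- pick(0.1); d50 <- pick(0.5); d90 <- pick(0.9)
  if (d50 == 0 || d90 == d10) {
    warning("degenerate distribution: SPAN set to 0")
    span <- 0
  } else span <- span_width(d10, d50, d90)
  structure(list(d10 = d10, d50 = d50, d90 = d90, d_avg = d_avg, span = span),
            class = "psd_summary")
}

#' @export
print.psd_summary <- function(x, ...) {
  cat(sprintf(
    "PSD: d(0.1) = %.1f, d(0.5) = %.1f, d(0.9) = %.1f um; d_avg = %.1f um; SPAN = %.2f\n",
    x$d10, x$d50, x$d90, x$d_avg, x$span))
  invisible(x)
}

#' Relative width (SPAN) of a particle-size distribution
#'
#' `SPAN = (d(0.9) - d(0.1)) / d(0.5)`; dimensionless and invariant to
#' rescaling all sizes by a common factor.
#'
#' @param d10,d50,d90 volume percentiles (um), `d10 <= d50 <= d90`, `d50 > 0`;
#'   vectorized.
#' @return SPAN (>= 0).
#' @examples
#' span_width(13.7, 85.0, 204.1)  # 2.24
#' @export
span_width <- function(d10, d50, d90) {
  if (any(d50 <= 0)) stop("d(0.5) must be positive")
  if (any(d10 > d50) || any(d50 > d90))
    stop("percentiles must satisfy d(0.1) <= d(0.5) <= d(0.9)")
  (d90 - d10) / d50
}

#' Gelatinization temperature range
#'
#' `dT = T_e - T_o`: the width of the starch gelatinization endotherm, from
#' onset to end temperature (the end temperature is sometimes written T_c;
#' it is canonicalized to T_e here).
#'
#' @param T_o onset temperature (deg C); vectorized.
#' @param T_e end (conclusion) temperature (deg C), `>= T_o`.
#' @param T_p optional peak temperature, checked to lie in `[T_o, T_e]`.
#' @return Temperature range dT (deg C).
#' @examples
#' dsc_delta(61.0, 69.8)  # 8.8
#' @export
dsc_delta <- function(T_o, T_e, T_p = NULL) {
  if (any(T_e < T_o)) stop("end temperature below onset temperature")
  if (!is.null(T_p) && (any(T_p < T_o) || any(T_p > T_e)))
    stop("peak temperature outside [T_o, T_e]")
  T_e - T_o
}
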