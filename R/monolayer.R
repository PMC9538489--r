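## Langmuir-trough compression isotherm processing --------------------------
##
## A monolayer spread at the air-water interface is compressed at constant
## rate while the surface pressure pi = gamma0 - gamma is recorded against
## the mean molecular area A. The in-plane stiffness is the compressibility
## modulus C^-1 = -A (dpi/dA)_T, high in condensed phases and dropping to
## zero at collapse, where compressed material is ejected from the
## interface at roughly constant pressure pi_c.

#' Build a compression isotherm
#'
#' Samples are normalized to compression order (strictly decreasing area);
#' duplicate-area samples are averaged. Small negative pressures from
#' sensor noise are tolerated down to -0.5 mN/m.
#'
#' @param areas Mean molecular areas (Angstrom^2 / molecule).
#' @param pressures Surface pressures pi (mN/m).
#' @param temperature Absolute temperature (K); default 295.15 (22 C).
#' @param compression_rate Barrier speed (cm^2/min), metadata only.
#' @return Object of class `compression_isotherm`: data frame with columns
#'   `area`, `pressure` in compression order.
#' @export
compression_isotherm <- function(areas, pressures, temperature = 295.15,
                                 compression_rate = NA_real_) {
  if (length(areas) != length(pressures)) {
    stop_invalid_input("area and pressure series must have equal length")
  }
  if (any(!is.finite(areas)) || any(areas <= 0)) {
    stop_invalid_input("areas must be finite and > 0")
  }
  if (any(!is.finite(pressures)) || any(pressures < -0.5)) {
    stop_invalid_input("pressures below -0.5 mN/m are not plausible sensor noise")
  }
  ## average duplicate areas, then order by decreasing area
  if (anyDuplicated(areas)) {
    pressures <- tapply(pressures, areas, mean)
    areas <- as.numeric(names(pressures))
    pressures <- as.numeric(pressures)
  }
  ord <- order(areas, decreasing = TRUE)
  out <- data.frame(area = areas[ord], pressure = pressures[ord])
  if (nrow(out) < 10L) {
    stop_invalid_input("need at least 10 distinct-area samples")
  }
  attr(out, "temperature") <- temperature
  attr(out, "compression_rate") <- compression_rate
  class(out) <- c("compression_isotherm", "data.frame")
  out
}

#' Mean molecular area from trough area and spread amount
#'
#' Divides the total surface area by the number of molecules spread on it
#' (amount of phosphorus times Avogadro's number); 1 cm^2 = 1e16 A^2.
#'
#' @param trough_area Total trough surface area (cm^2), > 0.
#' @param spread_amount Amount of phosphorus spread (mol), > 0.
#' @return Area per molecule (Angstrom^2).
#' @export
area_per_molecule <- function(trough_area, spread_amount) {
  if (any(!is.finite(trough_area)) || any(trough_area <= 0)) {
    stop_invalid_input("trough_area must be finite and > 0")
  }
  if (any(!is.finite(spread_amount)) || any(spread_amount <= 0)) {
    stop_invalid_input("spread_amount must be finite and > 0")
  }
  trough_area * 1e16 / (spread_amount * .N_AVOGADRO)
}

## Moving-window local-quadratic derivative dy/dx at each sample. Handles
## non-uniform spacing; windows are shifted (not shrunk) at the edges.
local_quad_deriv <- function(x, y, window) {
  n <- length(x)
  half <- window %/% 2L
  d <- numeric(n)
  for (i in seq_len(n)) {
    lo <- min(max(1L, i - half), n - window + 1L)
    sel <- lo:(lo + window - 1L)
    xc <- x[sel] - x[i]
    fit <- stats::.lm.fit(cbind(1, xc, xc * xc), y[sel])
    d[i] <- fit$coefficients[2L]
  }
  d
}

#' Compressibility-modulus profile of an isotherm
#'
#' Computes C^-1(A) = -A (dpi/dA) by a moving-window local quadratic
#' (Savitzky-Golay-style) derivative on the (A, pi) samples, which is
#' robust to sensor noise; returns the profile indexed by surface pressure.
#'
#' @param isotherm A [compression_isotherm()].
#' @param smoothing_window Odd number of samples in the derivative window;
#'   must satisfy `5 <= window <= n/2`.
#' @return Object of class `compressibility_profile`: data frame with
#'   columns `pressure`, `modulus`, `area` (compression order), with the
#'   window stored as an attribute.
#' @export
compressibility_profile <- function(isotherm, smoothing_window = 11L) {
  if (!inherits(isotherm, "compression_isotherm")) {
    stop_invalid_input("`isotherm` must be a compression_isotherm object")
  }
  w <- as.integer(smoothing_window)
  n <- nrow(isotherm)
  if (w %% 2L == 0L || w < 5L || w > n %/% 2L) {
    stop_invalid_input("smoothing_window must be odd, >= 5 and <= n/2")
  }
  dpi_da <- local_quad_deriv(isotherm$area, isotherm$pressure, w)
  out <- data.frame(
    pressure = isotherm$pressure,
    modulus = -isotherm$area * dpi_da,
    area = isotherm$area
  )
  attr(out, "smoothing_window") <- w
  attr(out, "temperature") <- attr(isotherm, "temperature")
  class(out) <- c("compressibility_profile", "data.frame")
  out
}

#' Maximum of the compressibility modulus in a pressure window
#'
#' @param profile A [compressibility_profile()].
#' @param pressure_window Length-2 numeric `(lo, hi)` in mN/m; only samples
#'   with pressure inside it are considered. Default: the full range.
#' @return List with `cinv_max` (mN/m), `pi_at_max` (mN/m), `area_at_max`,
#'   and `boundary` (TRUE when the maximum sits at an end of the windowed
#'   profile, i.e. a monotone profile). Ties break toward lower pressure.
#' @export
max_compressibility <- function(profile, pressure_window = NULL) {
  if (!inherits(profile, "compressibility_profile")) {
    stop_invalid_input("`profile` must be a compressibility_profile object")
  }
  if (is.null(pressure_window)) pressure_window <- range(profile$pressure)
  if (length(pressure_window) != 2L || pressure_window[1] > pressure_window[2]) {
    stop_invalid_input("pressure_window must be (lo, hi) with lo <= hi")
  }
  sel <- which(profile$pressure >= pressure_window[1] &
               profile$pressure <= pressure_window[2])
  if (length(sel) == 0L) {
    stop_invalid_input("pressure_window does not overlap the profile")
  }
  ord <- sel[order(profile$pressure[sel])]
  i <- ord[which.max(profile$modulus[ord])]  # first max = lowest pressure
  list(
    cinv_max = profile$modulus[i],
    pi_at_max = profile$pressure[i],
    area_at_max = profile$area[i],
    boundary = i == ord[1L] || i == ord[length(ord)]
  )
}

#' Lift-off area of a compression isotherm
#'
#' The largest molecular area at which the surface pressure first exceeds
#' `threshold` during compression, linearly interpolated between the
#' bracketing samples.
#'
#' @param isotherm A [compression_isotherm()].
#' @param threshold Pressure threshold (mN/m), default 0.5.
#' @return Lift-off area (Angstrom^2).
#' @export
lift_off_area <- function(isotherm, threshold = 0.5) {
  if (!inherits(isotherm, "compression_isotherm")) {
    stop_invalid_input("`isotherm` must be a compression_isotherm object")
  }
  p <- isotherm$pressure
  a <- isotherm$area
  above <- p > threshold
  if (!any(above) || !any(!above)) {
    stop_not_found("pressure never crosses the lift-off threshold from below")
  }
  i <- which(above & c(FALSE, !above[-length(above)]))[1]
  if (is.na(i)) {
    stop_not_found("no below-to-above threshold crossing during compression")
  }
  a[i - 1L] + (threshold - p[i - 1L]) * (a[i] - a[i - 1L]) / (p[i] - p[i - 1L])
}

#' Collapse point of a compression isotherm
#'
#' Collapse onset is the first sample beyond the compressibility-modulus
#' maximum where C^-1 falls below `drop_fraction` of that maximum (the
#' modulus drops toward zero on the collapse plateau).
#'
#' @param isotherm A [compression_isotherm()].
#' @param drop_fraction Fraction of the C^-1 maximum defining collapse
#'   onset; default 0.25.
#' @param smoothing_window Passed to [compressibility_profile()].
#' @return List with `pi_c` (collapse pressure, mN/m) and `area_collapse`
#'   (Angstrom^2).
#' @export
collapse_point <- function(isotherm, drop_fraction = 0.25,
                           smoothing_window = 11L) {
  if (drop_fraction <= 0 || drop_fraction >= 1) {
    stop_invalid_input("drop_fraction must lie in (0, 1)")
  }
  prof <- compressibility_profile(isotherm, smoothing_window)
  imax <- which.max(prof$modulus)
  beyond <- which(seq_len(nrow(prof)) > imax &
                  prof$modulus < drop_fraction * prof$modulus[imax])
  if (length(beyond) == 0L) {
    stop_not_found("isotherm ended before the collapse regime")
  }
  k <- beyond[1L]
  list(pi_c = prof$pressure[k], area_collapse = prof$area[k])
}
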