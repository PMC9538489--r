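## Micropipette aspiration analysis -----------------------------------------
##
## Aspirating a giant unilamellar vesicle (GUV) into a pipette of radius
## R_p at suction pressure dp sets the membrane tension
##
##     sigma = dp * R_p / (2 (1 - R_p / R_V))
##
## and the aspirated tongue of length L_p tracks the relative excess area
##
##     alpha = dL_p / (2 R_p) * ((R_p/R_V)^2 - (R_p/R_V)^3)
##
## measured against the reference (low-tension) step. In the entropic
## (low-tension) regime, pulling out thermal undulations gives the
## Canham-Helfrich relation ln(sigma/sigma0) ~ 8 pi kappa alpha / kBT, so
## the bending modulus kappa follows from the slope of ln(sigma/sigma0)
## against alpha.

#' Membrane tension from pipette geometry and suction pressure
#'
#' @param delta_p Suction pressure (Pa), > 0.
#' @param r_p Pipette radius (micrometres), 0 < r_p < r_v.
#' @param r_v Vesicle radius (micrometres).
#' @return Membrane tension sigma (mN/m).
#' @examples
#' membrane_tension(100, 4, 20) # 0.25 mN/m
#' @export
membrane_tension <- function(delta_p, r_p, r_v) {
  if (any(!is.finite(delta_p)) || any(delta_p <= 0)) {
    stop_invalid_input("delta_p must be finite and > 0")
  }
  if (any(!is.finite(r_p)) || any(!is.finite(r_v)) || any(r_p <= 0) ||
      any(r_p >= r_v)) {
    stop_invalid_input("radii must satisfy 0 < r_p < r_v (formula singular otherwise)")
  }
  ## Pa * m / 2(1 - ratio) = N/m; x 1000 -> mN/m
  1000 * delta_p * (r_p * 1e-6) / (2 * (1 - r_p / r_v))
}

#' Relative excess area from the protrusion-length change
#'
#' @param delta_lp Change in protrusion length relative to the reference
#'   step (micrometres), >= 0.
#' @param r_p Pipette radius (micrometres).
#' @param r_v Vesicle radius (micrometres), > r_p.
#' @return Relative excess area alpha (dimensionless).
#' @examples
#' excess_area(2, 4, 20) # 0.008
#' @export
excess_area <- function(delta_lp, r_p, r_v) {
  if (any(!is.finite(delta_lp)) || any(delta_lp < 0)) {
    stop_invalid_input("delta_lp must be finite and >= 0")
  }
  if (any(r_p <= 0) || any(r_p >= r_v)) {
    stop_invalid_input("radii must satisfy 0 < r_p < r_v")
  }
  x <- r_p / r_v
  delta_lp / (2 * r_p) * (x^2 - x^3)
}

#' Convert an aspiration step table to a (tension, excess-area) series
#'
#' The first step is the low-tension reference: sigma0 is its tension and
#' all protrusion-length changes are measured against its L_p. Each step
#' uses its own vesicle radius (aspiration shrinks the outer sphere). The
#' series is sorted by tension; a non-monotone suction sequence triggers a
#' warning, not an error.
#'
#' @param steps Data frame with columns `delta_p` (Pa), `lp` (um), `rp`
#'   (um), `rv` (um), one row per suction step in acquisition order; at
#'   least 4 steps, with the pipette radius constant within 1%.
#' @param temperature Absolute temperature (K), default 295.15.
#' @return Object of class `tension_area_series`: data frame with columns
#'   `tension` (mN/m) and `alpha`, plus `sigma0` and `temperature`
#'   attributes. The first (reference) row has `alpha = 0`.
#' @export
build_series <- function(steps, temperature = 295.15) {
  need <- c("delta_p", "lp", "rp", "rv")
  if (!is.data.frame(steps) || !all(need %in% names(steps))) {
    stop_invalid_input("`steps` must be a data frame with columns delta_p, lp, rp, rv")
  }
  if (nrow(steps) < 4L) stop_invalid_input("need at least 4 aspiration steps")
  if (any(steps$lp < 0)) stop_invalid_input("protrusion lengths must be >= 0")
  rp0 <- steps$rp[1L]
  if (any(abs(steps$rp - rp0) / rp0 > 0.01)) {
    stop_invalid_input("pipette radius varies by more than 1% across steps")
  }
  if (any(diff(steps$delta_p) <= 0)) {
    warning("suction pressures are not strictly increasing; sorting by tension")
  }
  sigma <- membrane_tension(steps$delta_p, steps$rp, steps$rv)
  ## signed protrusion change (noise can push a step slightly below the
  ## reference; clipping would bias the regression)
  dlp <- steps$lp - steps$lp[1L]
  x <- steps$rp / steps$rv
  alpha <- dlp / (2 * steps$rp) * (x^2 - x^3)
  ord <- order(sigma)
  out <- data.frame(tension = sigma[ord], alpha = alpha[ord])
  attr(out, "sigma0") <- out$tension[1L]
  attr(out, "temperature") <- temperature
  class(out) <- c("tension_area_series", "data.frame")
  out
}

#' Bending modulus from the entropic-regime Canham-Helfrich fit
#'
#' Ordinary least squares of `ln(sigma/sigma0)` on the excess area alpha
#' over the low-tension (entropic) regime `sigma <= max_tension`; the
#' bending modulus is `kappa = slope / (8 pi)` in units of kBT.
#'
#' @param series A [build_series()] result.
#' @param max_tension Upper tension bound of the entropic regime (mN/m),
#'   default 0.5; at least 4 points must fall inside it.
#' @return Object of class `bending_fit` with `kappa_kT`, `kappa_J`,
#'   `slope`, `slope_uncertainty`, `sigma0_fit` (intercept-implied
#'   reference tension, mN/m), `r_squared`, `n_points`, `temperature`.
#' @examples
#' sim <- gen_aspiration(kappa = 10, seed = 1)
#' fit_bending_modulus(build_series(sim$data))
#' @export
fit_bending_modulus <- function(series, max_tension = 0.5) {
  if (!inherits(series, "tension_area_series")) {
    stop_invalid_input("`series` must be a tension_area_series object")
  }
  sigma0 <- attr(series, "sigma0")
  temperature <- attr(series, "temperature")
  if (!is.finite(sigma0) || sigma0 <= 0) {
    stop_invalid_input("reference tension sigma0 must be > 0")
  }
  sel <- series$tension <= max_tension
  if (sum(sel) < 4L) {
    stop_invalid_input("fewer than 4 points in the entropic regime (sigma <= max_tension)")
  }
  y <- log(series$tension[sel] / sigma0)
  a <- series$alpha[sel]
  fit <- stats::lm(y ~ a)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)["a"])
  if (!is.finite(slope) || slope <= 0) {
    stop_fit_failure("non-positive slope: tension does not grow with excess area")
  }
  intercept <- unname(stats::coef(fit)["(Intercept)"])
  out <- list(
    kappa_kT = slope / (8 * pi),
    kappa_J = slope / (8 * pi) * .K_BOLTZMANN * temperature,
    slope = slope,
    slope_uncertainty = unname(sm$coefficients["a", "Std. Error"]),
    sigma0_fit = sigma0 * exp(intercept),
    r_squared = sm$r.squared,
    n_points = sum(sel),
    temperature = temperature
  )
  class(out) <- "bending_fit"
  out
}

#' @export
print.bending_fit <- function(x, ...) {
  cat("Canham-Helfrich entropic-regime bending fit\n")
  cat(sprintf("  kappa = %.2f kBT (%.3g J at %.2f K)\n",
              x$kappa_kT, x$kappa_J, x$temperature))
  cat(sprintf("  slope = %.1f (se %.2g), R^2 = %.4f, n = %d\n",
              x$slope, x$slope_uncertainty, x$r_squared, x$n_points))
  invisible(x)
}
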