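## FRAP analysis ------------------------------------------------------------
##
## After photobleaching a spot of radius w in a fluorescent supported
## bilayer, the normalized intensity recovers by lateral diffusion of
## unbleached probes following the hyperbolic model
##
##     f(t) = f0 + f_amp * (t / t_half) / (1 + t / t_half)
##
## so that f(t_half) = f0 + f_amp / 2 and the plateau is f0 + f_amp. The
## lateral diffusion coefficient follows as D = beta * w^2 / (4 * t_half),
## where beta corrects for beam shape and bleach depth.

#' Build a FRAP trace
#'
#' Raw per-frame intensities for the bleached region of interest, an
#' unbleached reference region (for acquisition-photobleaching correction)
#' and the background, with bleach metadata.
#'
#' @param times Acquisition times (s), strictly increasing.
#' @param roi Bleach-region mean intensity (arbitrary units).
#' @param reference Unbleached-region mean intensity (same units).
#' @param background Background intensity; scalar or per-frame series.
#' @param bleach_index Index of the first post-bleach frame.
#' @param bleach_radius Effective bleach-spot radius w (micrometres).
#' @return Object of class `frap_trace`.
#' @export
frap_trace <- function(times, roi, reference, background, bleach_index,
                       bleach_radius) {
  n <- length(times)
  if (length(background) == 1L) background <- rep(background, n)
  if (length(roi) != n || length(reference) != n || length(background) != n) {
    stop_invalid_input("times, roi, reference and background must have equal length")
  }
  if (n < 10L) stop_invalid_input("need at least 10 frames")
  if (any(diff(times) <= 0)) stop_invalid_input("times must be strictly increasing")
  bleach_index <- as.integer(bleach_index)
  if (bleach_index < 1L || bleach_index > n - 5L) {
    stop_invalid_input("bleach_index must satisfy 1 <= bleach_index <= n - 5")
  }
  check_scalar(bleach_radius, "bleach_radius")
  if (any(roi < background)) {
    stop_invalid_input("roi intensity falls below background")
  }
  out <- list(times = times, roi = roi, reference = reference,
              background = background, bleach_index = bleach_index,
              bleach_radius = bleach_radius)
  class(out) <- "frap_trace"
  out
}

#' Double-normalize a FRAP trace
#'
#' Standard double normalization: background subtraction, division by the
#' reference channel (correcting acquisition photobleaching), and rescaling
#' by the pre-bleach mean of the same ratio, so the pre-bleach level is
#' exactly 1. Output is restricted to post-bleach frames with time rebased
#' to the bleach frame (t = 0 at `bleach_index`).
#'
#' @param trace A [frap_trace()]; needs at least 3 pre-bleach frames.
#' @return Data frame with columns `time` (s, starting at 0) and `f`
#'   (normalized intensity).
#' @export
normalize_trace <- function(trace) {
  if (!inherits(trace, "frap_trace")) {
    stop_invalid_input("`trace` must be a frap_trace object")
  }
  if (trace$bleach_index < 4L) {
    stop_invalid_input("need at least 3 pre-bleach frames")
  }
  if (any(trace$reference <= trace$background)) {
    stop_invalid_input("reference intensity must exceed background everywhere")
  }
  ratio <- (trace$roi - trace$background) / (trace$reference - trace$background)
  pre <- seq_len(trace$bleach_index - 1L)
  f <- ratio / mean(ratio[pre])
  post <- seq(trace$bleach_index, length(ratio))
  data.frame(time = trace$times[post] - trace$times[trace$bleach_index],
             f = f[post])
}

## model used by fit_recovery
frap_model <- function(t, f0, f_amp, t_half) {
  f0 + f_amp * (t / t_half) / (1 + t / t_half)
}

#' Fit the hyperbolic recovery model to a normalized FRAP curve
#'
#' Least-squares fit of `f(t) = f0 + f_amp (t/t_half) / (1 + t/t_half)`.
#'
#' @param f Normalized recovery curve: a data frame with columns `time`
#'   and `f` (as returned by [normalize_trace()]), at least 8 points with
#'   the first below the last (a decreasing trace cannot be a recovery).
#' @return List with `f0`, `f_amp`, `t_half` (s) and `residual_rms`.
#' @export
fit_recovery <- function(f) {
  if (!is.data.frame(f) || !all(c("time", "f") %in% names(f))) {
    stop_invalid_input("`f` must be a data frame with columns time and f")
  }
  if (nrow(f) < 8L) stop_invalid_input("need at least 8 post-bleach points")
  if (f$f[1L] >= f$f[nrow(f)]) {
    stop_invalid_input("trace does not recover (first point >= last point)")
  }
  t <- f$time
  y <- f$f
  f0_0 <- max(min(y[1L], 0.95), 0)
  amp_0 <- max(max(y) - f0_0, 1e-3)
  half_level <- f0_0 + amp_0 / 2
  above <- which(y >= half_level)
  th_0 <- if (length(above) > 0 && above[1] > 1) t[above[1]] else stats::median(t[t > 0])
  th_0 <- max(th_0, diff(range(t)) / 100)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ f0 + f_amp * (t / t_half) / (1 + t / t_half),
      data = data.frame(t = t, y = y),
      start = list(f0 = f0_0, f_amp = amp_0, t_half = th_0),
      lower = c(f0 = 0, f_amp = 1e-6, t_half = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop_fit_failure(paste("recovery fit failed:",
                                               conditionMessage(e)))
  )
  p <- stats::coef(fit)
  list(f0 = unname(p["f0"]), f_amp = unname(p["f_amp"]),
       t_half = unname(p["t_half"]),
       residual_rms = sqrt(mean(stats::residuals(fit)^2)))
}

#' Lateral diffusion coefficient from the recovery half-time
#'
#' `D = beta * w^2 / (4 * t_half)`, where `beta` is the beam-shape /
#' bleach-depth correction factor (supplied, default 1).
#'
#' @param t_half Recovery half-time (s), > 0.
#' @param w Bleach-spot radius (micrometres), > 0.
#' @param beta Correction factor, > 0 (default 1).
#' @return Diffusion coefficient (micrometre^2 / s).
#' @export
diffusion_coefficient <- function(t_half, w, beta = 1) {
  check_scalar(t_half, "t_half")
  check_scalar(w, "w")
  check_scalar(beta, "beta")
  beta * w^2 / (4 * t_half)
}

#' Mobile fraction of a FRAP recovery
#'
#' The recovered fraction of the bleached signal,
#' `M = f_amp / (1 - f0)`, clipped to `[0, 1]`; the immobile fraction is
#' `1 - M`.
#'
#' @param f0 Normalized intensity just after bleach, in `[0, 1)`.
#' @param f_amp Recovery amplitude, >= 0.
#' @return Mobile fraction in `[0, 1]`.
#' @export
mobile_fraction <- function(f0, f_amp) {
  if (!is.finite(f0) || f0 < 0 || f0 >= 1) {
    stop_invalid_input("f0 must lie in [0, 1)")
  }
  if (!is.finite(f_amp) || f_amp < 0) {
    stop_invalid_input("f_amp must be >= 0")
  }
  min(max(f_amp / (1 - f0), 0), 1)
}

#' Full FRAP analysis of a raw trace
#'
#' Normalizes the trace, fits the hyperbolic recovery model and derives the
#' diffusion coefficient and mobile fraction.
#'
#' @param trace A [frap_trace()].
#' @param beta Beam-shape / bleach-depth correction factor (default 1).
#' @return Object of class `frap_fit` with `f0`, `f_amp`, `plateau`,
#'   `t_half`, `beta`, `diffusion_coefficient` (um^2/s),
#'   `mobile_fraction`, `residual_rms`.
#' @examples
#' sim <- gen_frap(seed = 1)
#' analyze_frap(sim$data)
#' @export
analyze_frap <- function(trace, beta = 1) {
  f <- normalize_trace(trace)
  fit <- fit_recovery(f)
  out <- c(fit[c("f0", "f_amp", "t_half")],
           list(plateau = fit$f0 + fit$f_amp,
                beta = beta,
                diffusion_coefficient = diffusion_coefficient(
                  fit$t_half, trace$bleach_radius, beta),
                mobile_fraction = mobile_fraction(fit$f0, fit$f_amp),
                residual_rms = fit$residual_rms))
  class(out) <- "frap_fit"
  out
}

#' @export
print.frap_fit <- function(x, ...) {
  cat("FRAP recovery fit\n")
  cat(sprintf("  f0 = %.3f, amplitude = %.3f (plateau %.3f)\n",
              x$f0, x$f_amp, x$plateau))
  cat(sprintf("  t_half = %.3g s, beta = %.2f\n", x$t_half, x$beta))
  cat(sprintf("  D = %.3g um^2/s, mobile fraction = %.2f\n",
              x$diffusion_coefficient, x$mobile_fraction))
  invisible(x)
}
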