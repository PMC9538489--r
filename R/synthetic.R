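## Synthetic-data generators ------------------------------------------------
##
## Every input type the package analyzes can be simulated from known
## ground-truth parameters under a stated noise model, so each analysis
## stage is testable by parameter recovery without external data. All
## generators are seeded; identical (parameters, seed) give identical
## output, and each returns a `truth` record holding every generating
## parameter alongside the data object.

maybe_seed <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L) {
      stop_invalid_spec("seed must be a single integer")
    }
    set.seed(as.integer(seed))
  }
}

#' Named parameter presets for the bundled lipid-extract systems
#'
#' Ground-truth presets for demonstration and recovery runs, modelled on
#' outer (OMM) and inner (IMM) mitochondrial-membrane lipid extracts and a
#' POPC control: adsorption parameters (gamma0, Gamma_inf, K, CMC),
#' isotherm shape (lift-off area, compressibility maximum and its
#' pressure, collapse pressure), FRAP diffusion coefficient, bending
#' modulus, GUV phase-separation probability and TLC composition.
#'
#' @param name One of `"OMM"`, `"IMM"`, `"POPC"`.
#' @return Nested list of per-technique parameter lists (components set to
#'   `NULL` where a technique does not apply to the preset).
#' @export
membrane_preset <- function(name = c("OMM", "IMM", "POPC")) {
  name <- match.arg(name)
  switch(name,
    OMM = list(
      adsorption = list(gamma0 = 72, gamma_inf_conc = 3.0e-6, k_ads = 0.42,
                        cmc = 23, gamma_min = 46),
      isotherm = list(lift_off = 90, cinv_max = 150, pi_at_max = 35, pi_c = 43),
      frap = list(d_coeff = 0.8),
      aspiration = list(kappa = 7.8),
      guv = list(phase_prob = 0.90, n = 261),
      composition = c(PC = 35.0, PE = 41.0, CL = 1.0, SM = 6.3, Chol = 16.7)
    ),
    IMM = list(
      adsorption = list(gamma0 = 72, gamma_inf_conc = 2.4e-6, k_ads = 0.15,
                        cmc = 50, gamma_min = 46),
      isotherm = list(lift_off = 140, cinv_max = 80, pi_at_max = 32, pi_c = 40),
      frap = list(d_coeff = 1.1),
      aspiration = list(kappa = 5.6),
      guv = list(phase_prob = 0.02, n = 312),
      composition = c(PC = 27.4, PE = 34.4, CL = 21.0, SM = 1.6, PI = 2.2,
                      PS = 2.4, Chol = 10.3, LPC = 0.7)
    ),
    POPC = list(
      adsorption = NULL,
      isotherm = list(lift_off = 100, cinv_max = 100, pi_at_max = 33, pi_c = 45),
      frap = list(d_coeff = 1.8),
      aspiration = list(kappa = 10),
      guv = list(phase_prob = 0, n = 237),
      composition = c(POPC = 100)
    )
  )
}

#' Simulate an adsorption (surface tension vs concentration) dataset
#'
#' Concentrations are log-spaced on `conc_range`; tensions follow the
#' Gibbs-Langmuir equation of state, clamped at `gamma_min` beyond the
#' micellization plateau when a `cmc` is supplied (the clamp level is the
#' model tension at the CMC, so the curve is continuous), plus additive
#' Gaussian noise.
#'
#' @param gamma0 Bare-interface tension (mN/m), default 72.
#' @param gamma_inf_conc Maximum surface concentration (mol/m^2), default
#'   3.0e-6.
#' @param k_ads Adsorption constant (nM^-1), default 0.42.
#' @param cmc Optional CMC (nM); the tension plateaus beyond it.
#' @param n Number of concentrations, default 20.
#' @param conc_range Concentration range (nM), default c(0.1, 200).
#' @param noise_sd Additive Gaussian tension noise (mN/m), default 0.2
#'   (typical Wilhelmy-plate precision).
#' @param temperature Kelvin, default 295.15.
#' @param seed Integer seed (NULL leaves the RNG state untouched).
#' @return List with `data` (an [adsorption_data()]) and `truth`.
#' @export
gen_adsorption <- function(gamma0 = 72, gamma_inf_conc = 3.0e-6,
                           k_ads = 0.42, cmc = NULL, n = 20,
                           conc_range = c(0.1, 200), noise_sd = 0.2,
                           temperature = 295.15, seed = NULL) {
  check_scalar(gamma0, "gamma0")
  check_scalar(gamma_inf_conc, "gamma_inf_conc")
  check_scalar(k_ads, "k_ads")
  if (!is.null(cmc)) {
    check_scalar(cmc, "cmc")
    if (cmc <= conc_range[1L]) {
      stop_invalid_spec("cmc must exceed the smallest generated concentration")
    }
  }
  maybe_seed(seed)
  conc <- exp(seq(log(conc_range[1L]), log(conc_range[2L]), length.out = n))
  gam <- eval_gibbs_langmuir(gamma0, gamma_inf_conc, k_ads, conc, temperature)
  if (!is.null(cmc)) {
    gamma_min <- eval_gibbs_langmuir(gamma0, gamma_inf_conc, k_ads, cmc,
                                     temperature)
    gam <- pmax(gam, gamma_min)
  }
  if (noise_sd > 0) gam <- gam + stats::rnorm(n, 0, noise_sd)
  list(
    data = adsorption_data(conc, pmin(pmax(gam, 1e-3), 100), temperature),
    truth = list(kind = "adsorption", gamma0 = gamma0,
                 gamma_inf_conc = gamma_inf_conc, k_ads = k_ads, cmc = cmc,
                 n = n, conc_range = conc_range, noise_sd = noise_sd,
                 temperature = temperature, seed = seed)
  )
}

## Piecewise-lognormal compressibility bump underlying gen_isotherm:
## C^-1(A) = cinv_max * exp(-(log A - mu)^2 / (2 s(A)^2)) with width s_r on
## the large-area (rise) side and s_l on the small-area (collapse) side.
## Integrating pi'(A) = -C^-1(A)/A in log-area gives a closed form in
## pnorm, so the generated isotherm has an exact symbolic C^-1 oracle.
iso_shape <- function(lift_off, cinv_max, pi_at_max, pi_c, lift_threshold = 0.5) {
  if (pi_c <= pi_at_max) {
    stop_invalid_spec("collapse pressure must exceed the pressure at the C^-1 maximum")
  }
  if (pi_at_max <= lift_threshold) {
    stop_invalid_spec("pi_at_max must exceed the lift-off threshold")
  }
  k <- sqrt(pi / 2)  # integral of a half-Gaussian of unit sd is sqrt(pi/2)
  s_r <- pi_at_max / (cinv_max * k)
  s_l <- (pi_c - pi_at_max) / (cinv_max * k)
  ## place the bump centre so that pi(lift_off) equals the lift threshold
  tail_frac <- lift_threshold / (2 * pi_at_max)
  mu <- log(lift_off) - stats::qnorm(1 - tail_frac) * s_r
  pi_fun <- function(a) {
    u <- log(a)
    right <- 2 * pi_at_max * stats::pnorm(mu, mean = pmax(u, mu), sd = s_r)
    left <- ifelse(u < mu,
                   2 * (pi_c - pi_at_max) *
                     (stats::pnorm(mu, mean = u, sd = s_l) - 0.5),
                   0)
    right + left
  }
  cinv_fun <- function(a) {
    u <- log(a)
    s <- ifelse(u >= mu, s_r, s_l)
    cinv_max * exp(-(u - mu)^2 / (2 * s^2))
  }
  list(mu = mu, s_r = s_r, s_l = s_l, pi_fun = pi_fun, cinv_fun = cinv_fun)
}

#' Simulate a compression isotherm with a symbolic compressibility oracle
#'
#' The surface pressure is built from a differentiable parametric form: a
#' piecewise-lognormal compressibility bump in log-area, integrated in
#' closed form. The analytic C^-1(A) = -A pi'(A) is returned alongside the
#' samples, so numerical differentiation schemes can be validated exactly.
#' Gaussian pressure noise is added on request.
#'
#' @param lift_off Lift-off area (Angstrom^2): pressure crosses 0.5 mN/m
#'   there. Default 90.
#' @param cinv_max Target maximum of C^-1 (mN/m), default 150.
#' @param pi_at_max Pressure at the C^-1 maximum (mN/m), default 35.
#' @param pi_c Collapse (plateau) pressure (mN/m), must exceed
#'   `pi_at_max`; default 43.
#' @param n Number of samples (uniform in area), default 800 (a one-hour
#'   compression at typical trough logging rates); the 11-point derivative
#'   window then spans well under half of the narrow collapse flank.
#' @param area_range Optional c(min, max) area range; by default from 15%
#'   above lift-off down to deep collapse.
#' @param noise_sd Additive Gaussian pressure noise (mN/m), default 0.
#' @param temperature Kelvin, default 295.15.
#' @param seed Integer seed.
#' @return List with `data` (a [compression_isotherm()]), `pi_fun`,
#'   `cinv_fun` (symbolic oracles, functions of area) and `truth`.
#' @export
gen_isotherm <- function(lift_off = 90, cinv_max = 150, pi_at_max = 35,
                         pi_c = 43, n = 800, area_range = NULL,
                         noise_sd = 0, temperature = 295.15, seed = NULL) {
  shape <- iso_shape(lift_off, cinv_max, pi_at_max, pi_c)
  maybe_seed(seed)
  if (is.null(area_range)) {
    area_range <- c(exp(shape$mu - 6 * shape$s_l), lift_off * 1.15)
  }
  areas <- seq(area_range[2L], area_range[1L], length.out = n)
  pressures <- shape$pi_fun(areas)
  if (noise_sd > 0) pressures <- pressures + stats::rnorm(n, 0, noise_sd)
  list(
    data = compression_isotherm(areas, pmax(pressures, -0.49), temperature,
                                compression_rate = 10),
    pi_fun = shape$pi_fun,
    cinv_fun = shape$cinv_fun,
    truth = list(kind = "isotherm", lift_off = lift_off, cinv_max = cinv_max,
                 pi_at_max = pi_at_max, pi_c = pi_c, n = n,
                 area_range = area_range, noise_sd = noise_sd,
                 temperature = temperature, seed = seed)
  )
}

#' Simulate a raw FRAP trace
#'
#' Pre-bleach frames sit at the unbleached level; post-bleach frames
#' follow the hyperbolic recovery model. Both the bleached-spot and the
#' reference channel decay exponentially with acquisition time
#' (acquisition photobleaching), and Gaussian intensity noise is added to
#' each channel (the reference region averages many more pixels, so its
#' noise is one fifth of the spot noise).
#'
#' @param f0 Normalized intensity just after bleach, default 0.3.
#' @param f_amp Recovery amplitude, default 0.6.
#' @param t_half Recovery half-time (s), default 2.
#' @param bleach_radius Bleach-spot radius w (micrometres), default 2.
#' @param beta Correction factor recorded in the truth record (default 1);
#'   the implied diffusion coefficient is `beta w^2 / (4 t_half)`.
#' @param n_pre,n_post Number of pre-/post-bleach frames (10, 360).
#' @param dt Frame interval (s), default 0.25.
#' @param acq_bleach_tau Exponential acquisition-bleaching time constant
#'   (s, `Inf` disables), default 150.
#' @param noise_sd Gaussian noise sd on the normalized-intensity scale,
#'   default 0.02.
#' @param scale,background Intensity scale of the signal and constant
#'   background offset (arbitrary units), defaults 1000 and 100.
#' @param seed Integer seed.
#' @return List with `data` (a [frap_trace()]) and `truth` (including the
#'   implied `d_coeff`).
#' @export
gen_frap <- function(f0 = 0.3, f_amp = 0.6, t_half = 2, bleach_radius = 2,
                     beta = 1, n_pre = 10, n_post = 360, dt = 0.25,
                     acq_bleach_tau = 150, noise_sd = 0.02,
                     scale = 1000, background = 100, seed = NULL) {
  if (f0 < 0 || f0 >= 1) stop_invalid_spec("f0 must lie in [0, 1)")
  if (f_amp <= 0) stop_invalid_spec("f_amp must be > 0")
  if (f0 + f_amp > 1 + 1e-9) stop_invalid_spec("plateau f0 + f_amp cannot exceed 1")
  check_scalar(t_half, "t_half")
  check_scalar(bleach_radius, "bleach_radius")
  maybe_seed(seed)
  n <- n_pre + n_post
  times <- seq(0, by = dt, length.out = n)
  t_post <- times[(n_pre + 1L):n] - times[n_pre + 1L]
  f_true <- c(rep(1, n_pre), frap_model(t_post, f0, f_amp, t_half))
  decay <- exp(-times / acq_bleach_tau)
  roi <- background + scale * f_true * decay
  reference <- background + scale * decay
  if (noise_sd > 0) {
    roi <- roi + stats::rnorm(n, 0, noise_sd * scale)
    reference <- reference + stats::rnorm(n, 0, noise_sd * scale / 5)
  }
  roi <- pmax(roi, background)
  list(
    data = frap_trace(times, roi, reference, background,
                      bleach_index = n_pre + 1L,
                      bleach_radius = bleach_radius),
    truth = list(kind = "frap", f0 = f0, f_amp = f_amp, t_half = t_half,
                 bleach_radius = bleach_radius, beta = beta,
                 d_coeff = beta * bleach_radius^2 / (4 * t_half),
                 mobile_fraction = min(f_amp / (1 - f0), 1),
                 n_pre = n_pre, n_post = n_post, dt = dt,
                 acq_bleach_tau = acq_bleach_tau, noise_sd = noise_sd,
                 seed = seed)
  )
}

#' Simulate a micropipette-aspiration step table
#'
#' A tension staircase is laid out log-spaced between `sigma0` and
#' `sigma_max` (the entropic regime); the Canham-Helfrich relation with
#' the requested bending modulus gives each step's excess area, which is
#' inverted through the pipette geometry to protrusion lengths, and the
#' tension formula to suction pressures. Optional multiplicative Gaussian
#' noise perturbs the protrusion lengths.
#'
#' @param kappa Bending modulus (kBT), default 5.6.
#' @param sigma0 Reference (first-step) tension (mN/m), default 0.005.
#' @param sigma_max Largest staircase tension (mN/m), default 0.4. A value
#'   above `max_tension_warn` leaves a note in the truth record.
#' @param n Number of steps, default 12.
#' @param r_p,r_v Pipette and initial vesicle radius (micrometres; 4, 20).
#' @param lp0 Reference protrusion length (micrometres), default 2.
#' @param shrink_rv If TRUE (default), each step's vesicle radius is
#'   reduced to conserve volume as the tongue grows.
#' @param noise_frac Multiplicative Gaussian noise sd on protrusion
#'   lengths (e.g. 0.05 for 5%), default 0.
#' @param max_tension_warn Entropic-regime bound used for the truth-record
#'   note (mN/m), default 0.5.
#' @param temperature Kelvin, default 295.15.
#' @param seed Integer seed.
#' @return List with `data` (a step data frame for [build_series()]) and
#'   `truth`.
#' @export
gen_aspiration <- function(kappa = 5.6, sigma0 = 0.005, sigma_max = 0.4,
                           n = 12, r_p = 4, r_v = 20, lp0 = 2,
                           shrink_rv = TRUE, noise_frac = 0,
                           max_tension_warn = 0.5,
                           temperature = 295.15, seed = NULL) {
  check_scalar(kappa, "kappa")
  check_scalar(sigma0, "sigma0")
  check_scalar(sigma_max, "sigma_max")
  if (sigma_max <= sigma0) stop_invalid_spec("sigma_max must exceed sigma0")
  if (r_p >= r_v) stop_invalid_spec("pipette radius must be below vesicle radius")
  maybe_seed(seed)
  sigma <- exp(seq(log(sigma0), log(sigma_max), length.out = n))
  alpha <- log(sigma / sigma0) / (8 * pi * kappa)
  ## geometry inversion with per-step vesicle radius
  rv_i <- numeric(n)
  lp <- numeric(n)
  rv_cur <- r_v
  for (i in seq_len(n)) {
    x <- r_p / rv_cur
    dlp <- alpha[i] * 2 * r_p / (x^2 - x^3)
    lp[i] <- lp0 + dlp
    rv_i[i] <- rv_cur
    if (shrink_rv && i < n) {
      ## conserve volume: the tongue (cylinder + cap) grows at the
      ## expense of the outer sphere
      dv <- pi * r_p^2 * (dlp - if (i > 1) lp[i - 1L] - lp0 else 0)
      rv_cur <- max((rv_cur^3 - 3 * dv / (4 * pi))^(1 / 3), r_p * 1.5)
    }
  }
  delta_p <- 2 * (sigma / 1000) * (1 - r_p / rv_i) / (r_p * 1e-6)
  if (noise_frac > 0) lp <- lp * (1 + stats::rnorm(n, 0, noise_frac))
  note <- if (sigma_max > max_tension_warn) {
    "staircase exceeds the nominal entropic-regime bound"
  } else NULL
  list(
    data = data.frame(delta_p = delta_p, lp = lp, rp = r_p, rv = rv_i),
    truth = list(kind = "aspiration", kappa = kappa, sigma0 = sigma0,
                 sigma_max = sigma_max, n = n, r_p = r_p, r_v = r_v,
                 lp0 = lp0, shrink_rv = shrink_rv, noise_frac = noise_frac,
                 temperature = temperature, seed = seed, note = note)
  )
}

#' Simulate a TLC densitometry lane
#'
#' Spot intensities are the ground-truth percentages times a lane gain,
#' perturbed by multiplicative Gaussian noise.
#'
#' @param percentages Named numeric vector summing to 100 (default: the
#'   OMM preset composition).
#' @param lane_gain Arbitrary intensity per percent, default 1000.
#' @param noise_frac Multiplicative Gaussian noise sd, default 0.05.
#' @param seed Integer seed.
#' @return List with `data` (a [densitometry_table()]) and `truth`.
#' @export
gen_densitometry <- function(percentages = membrane_preset("OMM")$composition,
                             lane_gain = 1000, noise_frac = 0.05,
                             seed = NULL) {
  if (is.null(names(percentages)) || any(percentages < 0)) {
    stop_invalid_spec("percentages must be a named non-negative vector")
  }
  if (abs(sum(percentages) - 100) > 1e-6) {
    stop_invalid_spec("percentages must sum to 100")
  }
  maybe_seed(seed)
  intens <- percentages * lane_gain
  if (noise_frac > 0) {
    intens <- pmax(intens * (1 + stats::rnorm(length(intens), 0, noise_frac)), 0)
  }
  list(
    data = densitometry_table(names(percentages), as.numeric(intens)),
    truth = list(kind = "densitometry", percentages = percentages,
                 lane_gain = lane_gain, noise_frac = noise_frac, seed = seed)
  )
}

#' Simulate a GUV population
#'
#' Diameters are log-normal (giant vesicles typically peak above 10
#' micrometres); phase-separation flags are Bernoulli.
#'
#' @param n Number of vesicles, default 261.
#' @param meanlog,sdlog Log-normal parameters of the diameter
#'   distribution; defaults log(13) and 0.45 give a median of 13 um with
#'   a realistic 5-60 um spread.
#' @param phase_prob Probability that a vesicle is phase-separated,
#'   default 0.9.
#' @param seed Integer seed.
#' @return List with `data` (a [guv_population()]) and `truth`.
#' @export
gen_guv <- function(n = 261, meanlog = log(13), sdlog = 0.45,
                    phase_prob = 0.9, seed = NULL) {
  if (n < 1 || sdlog <= 0 || phase_prob < 0 || phase_prob > 1) {
    stop_invalid_spec("need n >= 1, sdlog > 0 and phase_prob in [0, 1]")
  }
  maybe_seed(seed)
  d <- stats::rlnorm(n, meanlog, sdlog)
  flags <- stats::runif(n) < phase_prob
  list(
    data = guv_population(d, flags),
    truth = list(kind = "guv", n = n, meanlog = meanlog, sdlog = sdlog,
                 median = exp(meanlog), phase_prob = phase_prob, seed = seed)
  )
}
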