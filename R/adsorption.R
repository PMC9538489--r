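## Gibbs-Langmuir adsorption analysis ---------------------------------------
##
## A dilute, non-ionic surfactant adsorbing at the air-water interface obeys
## the Gibbs-Langmuir equation of state
##
##     gamma(c) = gamma0 - R T Gamma_inf ln(1 + K c)
##
## with gamma0 the bare-interface tension, Gamma_inf the maximum surface
## (excess) concentration (mol/m^2) and K the adsorption equilibrium
## constant. Above the critical micelle concentration (CMC) the tension
## plateaus and the equation no longer applies; the fit therefore excludes
## plateau points. Concentrations here are in nM (so K is nM^-1) and
## tensions in mN/m.

#' Build an adsorption dataset
#'
#' Pairs of bulk surfactant (lipid) concentration and equilibrium surface
#' tension measured e.g. with a Wilhelmy plate, at a fixed temperature.
#' Points are sorted by increasing concentration.
#'
#' @param concentrations Bulk concentrations (nM), non-negative.
#' @param tensions Equilibrium surface tensions (mN/m), in (0, 100].
#' @param temperature Absolute temperature (K); default 295.15 K (22 C).
#' @return An object of class `adsorption_data`: a data frame with columns
#'   `concentration` and `tension`, plus a `temperature` attribute.
#' @examples
#' d <- adsorption_data(c(1, 5, 20, 80), c(70, 62, 52, 47))
#' @export
adsorption_data <- function(concentrations, tensions,
                            temperature = 295.15) {
  if (length(concentrations) != length(tensions)) {
    stop_invalid_input("concentration and tension series must have equal length")
  }
  if (length(concentrations) < 4L) {
    stop_invalid_input("need at least 4 (concentration, tension) points")
  }
  if (any(!is.finite(concentrations)) || any(concentrations < 0)) {
    stop_invalid_input("concentrations must be finite and >= 0")
  }
  if (any(!is.finite(tensions)) || any(tensions <= 0) || any(tensions > 100)) {
    stop_invalid_input("tensions must lie in (0, 100] mN/m")
  }
  check_scalar(temperature, "temperature")
  if (temperature < 273 || temperature > 330) {
    stop_invalid_input("temperature must lie in [273, 330] K")
  }
  ord <- order(concentrations)
  conc <- concentrations[ord]
  if (any(diff(conc) <= 0)) {
    stop_invalid_input("concentrations must be distinct (strictly increasing after sorting)")
  }
  out <- data.frame(concentration = conc, tension = tensions[ord])
  attr(out, "temperature") <- temperature
  class(out) <- c("adsorption_data", "data.frame")
  out
}

#' Evaluate the Gibbs-Langmuir equation of state
#'
#' @param gamma0 Bare-interface surface tension (mN/m).
#' @param gamma_inf_conc Maximum surface concentration Gamma_inf (mol/m^2).
#' @param k_ads Adsorption equilibrium constant K (nM^-1).
#' @param c Bulk concentration(s) (nM), >= 0.
#' @param temperature Absolute temperature (K).
#' @return Surface tension(s) in mN/m. Monotonically non-increasing in `c`.
#' @examples
#' eval_gibbs_langmuir(72, 3.0e-6, 0.42, 50)
#' @export
eval_gibbs_langmuir <- function(gamma0, gamma_inf_conc, k_ads, c,
                                temperature = 295.15) {
  check_scalar(gamma0, "gamma0")
  check_scalar(gamma_inf_conc, "gamma_inf_conc")
  check_scalar(k_ads, "k_ads")
  check_scalar(temperature, "temperature")
  if (any(!is.finite(c)) || any(c < 0)) {
    stop_invalid_input("concentrations must be finite and >= 0")
  }
  # R T Gamma_inf is in N/m; x 1000 converts to mN/m
  a <- 1000 * .R_GAS * temperature * gamma_inf_conc
  gamma0 - a * log1p(k_ads * c)
}

#' Mean molecular area from the maximum surface concentration
#'
#' At maximum packing each molecule occupies A = 1 / (Gamma_inf N_A);
#' 1 m^2 = 1e20 Angstrom^2.
#'
#' @param gamma_inf_conc Maximum surface concentration (mol/m^2), > 0.
#' @return Mean molecular area in Angstrom^2.
#' @examples
#' mean_molecular_area(3.0e-6) # ~55 A^2
#' @export
mean_molecular_area <- function(gamma_inf_conc) {
  if (any(!is.finite(gamma_inf_conc)) || any(gamma_inf_conc <= 0)) {
    stop_invalid_input("gamma_inf_conc must be finite and > 0")
  }
  1e20 / (gamma_inf_conc * .N_AVOGADRO)
}

## Trailing-plateau detection, two-phase. Phase 1 finds the maximal
## trailing run of tensions all within `tol` of the run mean (a single
## point is never a plateau). Phase 2 grows the run backward against the
## running plateau level: a preceding point joins while it lies below
## level + tol (the level is re-estimated as the run mean after each
## addition). The second phase matters on noisy data, where scatter breaks
## the strict phase-1 criterion well before the true plateau onset.
detect_plateau <- function(tensions, tol) {
  n <- length(tensions)
  run <- n
  for (i in seq(n - 1L, 1L)) {
    cand <- tensions[i:n]
    if (all(abs(cand - mean(cand)) <= tol)) run <- i else break
  }
  if (run >= n) return(integer(0))
  level <- mean(tensions[run:n])
  while (run > 1L && tensions[run - 1L] <= level + tol) {
    run <- run - 1L
    level <- mean(tensions[run:n])
  }
  seq(run, n)
}

#' Fit the Gibbs-Langmuir equation to adsorption data
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `gamma = gamma0 - R T Gamma_inf ln(1 + K c)` to the adsorption branch of
#' the dataset. Trailing plateau points (micellization regime, where the
#' equation of state does not hold) are excluded before fitting: the
#' trailing run of tensions within `2 * noise_sd` of the plateau level is
#' dropped when it contains at least two points.
#'
#' @param dataset An [adsorption_data()] object.
#' @param init Optional named list / vector with starting values
#'   `gamma0`, `gamma_inf_conc`, `k_ads`. Defaults: the lowest-concentration
#'   tension, 2e-6 mol/m^2, and 1/median(concentration).
#' @param fix_gamma0 Optional value (mN/m) at which gamma0 is held fixed
#'   (e.g. 72.0 for pure water near room temperature).
#' @param max_conc Optional concentration cutoff (nM); points above it are
#'   excluded from the fit (caller-supplied plateau exclusion).
#' @param noise_sd Measurement standard deviation of the tensiometer
#'   (mN/m); used only for plateau exclusion. Default 0.2.
#' @param cmc_method Method forwarded to [estimate_cmc()]; the CMC is
#'   reported as `NA` when undefined (no plateau).
#' @return An object of class `gibbs_langmuir_fit` with elements `gamma0`,
#'   `gamma_inf_conc`, `k_ads`, `param_uncertainties` (one-sigma, from the
#'   linearized covariance at the optimum), `residual_rms`, `mean_area`
#'   (Angstrom^2), `cmc` (nM or NA), `n_points`, `temperature`.
#' @examples
#' sim <- gen_adsorption(seed = 1)
#' fit <- fit_gibbs_langmuir(sim$data)
#' @export
fit_gibbs_langmuir <- function(dataset, init = NULL, fix_gamma0 = NULL,
                               max_conc = NULL, noise_sd = 0.2,
                               cmc_method = c("two-segment", "plateau-intersection")) {
  if (!inherits(dataset, "adsorption_data")) {
    stop_invalid_input("`dataset` must be an adsorption_data object")
  }
  cmc_method <- match.arg(cmc_method)
  temperature <- attr(dataset, "temperature")
  conc <- dataset$concentration
  tens <- dataset$tension

  keep <- rep(TRUE, length(conc))
  if (!is.null(max_conc)) keep <- keep & conc <= max_conc
  ## drop the trailing micellization plateau (tensions within 2 sd of the
  ## plateau level); a lone low endpoint is not a plateau
  low <- which(keep)
  plateau <- detect_plateau(tens[low], tol = 2 * noise_sd)
  if (length(plateau) >= 2L) keep[low[plateau]] <- FALSE
  cf <- conc[keep]
  tf <- tens[keep]
  if (length(cf) < 4L) {
    stop_invalid_input("fewer than 4 points remain on the adsorption branch")
  }

  ## internal parameterization: a = 1000 R T Gamma_inf (mN/m), K (nM^-1)
  to_a <- 1000 * .R_GAS * temperature
  start <- list(
    g0 = if (!is.null(init$gamma0)) init$gamma0 else tf[1],
    a  = to_a * (if (!is.null(init$gamma_inf_conc)) init$gamma_inf_conc else 2e-6),
    K  = if (!is.null(init$k_ads)) init$k_ads else 1 / stats::median(cf[cf > 0])
  )

  df <- data.frame(c = cf, g = tf)
  fit1 <- function(st) {
    if (is.null(fix_gamma0)) {
      minpack.lm::nlsLM(g ~ g0 - a * log1p(K * c), data = df,
                        start = st,
                        lower = c(g0 = 1, a = 1e-8, K = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      df$g0 <- fix_gamma0
      minpack.lm::nlsLM(g ~ g0 - a * log1p(K * c), data = df,
                        start = st[c("a", "K")],
                        lower = c(a = 1e-8, K = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }
  ## documented restarts: K scaled by 0.2 and 5 if the first attempt fails
  attempts <- list(start,
                   modifyList(start, list(K = start$K * 0.2)),
                   modifyList(start, list(K = start$K * 5)))
  fit <- NULL
  best_resid <- Inf
  for (st in attempts) {
    res <- tryCatch(fit1(st), error = function(e) e)
    if (!inherits(res, "error")) { fit <- res; break }
  }
  if (is.null(fit)) {
    stop_fit_failure("Gibbs-Langmuir fit did not converge after 3 restarts",
                     best_residual = best_resid)
  }

  co <- summary(fit)$coefficients
  g0_hat <- if (is.null(fix_gamma0)) co["g0", "Estimate"] else fix_gamma0
  a_hat <- co["a", "Estimate"]
  k_hat <- co["K", "Estimate"]
  se <- c(
    gamma0 = if (is.null(fix_gamma0)) co["g0", "Std. Error"] else 0,
    gamma_inf_conc = co["a", "Std. Error"] / to_a,
    k_ads = co["K", "Std. Error"]
  )
  ginf_hat <- a_hat / to_a
  resid_rms <- sqrt(mean(stats::residuals(fit)^2))

  cmc <- tryCatch(
    estimate_cmc(dataset, method = cmc_method, noise_sd = noise_sd),
    memmech_undefined_cmc = function(e) NA_real_,
    memmech_fit_failure = function(e) NA_real_
  )

  out <- list(
    gamma0 = g0_hat,
    gamma_inf_conc = ginf_hat,
    k_ads = k_hat,
    param_uncertainties = se,
    residual_rms = resid_rms,
    mean_area = mean_molecular_area(ginf_hat),
    cmc = cmc,
    cmc_method = cmc_method,
    n_points = length(cf),
    temperature = temperature
  )
  class(out) <- "gibbs_langmuir_fit"
  out
}

#' @export
print.gibbs_langmuir_fit <- function(x, ...) {
  cat("Gibbs-Langmuir adsorption fit\n")
  cat(sprintf("  gamma0     : %.2f mN/m (se %.3g)\n", x$gamma0,
              x$param_uncertainties["gamma0"]))
  cat(sprintf("  Gamma_inf  : %.3g mol/m^2 (se %.2g)\n", x$gamma_inf_conc,
              x$param_uncertainties["gamma_inf_conc"]))
  cat(sprintf("  K          : %.3g nM^-1 (se %.2g)\n", x$k_ads,
              x$param_uncertainties["k_ads"]))
  cat(sprintf("  mean area  : %.1f A^2/molecule\n", x$mean_area))
  cat(sprintf("  CMC        : %s nM (%s)\n",
              ifelse(is.na(x$cmc), "undefined", sprintf("%.3g", x$cmc)),
              x$cmc_method))
  cat(sprintf("  residual rms %.3g mN/m on %d points at %.2f K\n",
              x$residual_rms, x$n_points, x$temperature))
  invisible(x)
}

#' Estimate the critical micelle concentration
#'
#' Two estimators of the concentration at which the surface tension reaches
#' its micellization plateau. `two-segment` fits a continuous piecewise
#' model -- the Gibbs-Langmuir branch joined at a candidate breakpoint to a
#' constant equal to the branch value there -- at every candidate breakpoint
#' (the observed concentrations) and returns the breakpoint minimizing the
#' total squared error. `plateau-intersection` fits the branch to
#' non-plateau points and solves for the concentration where the fitted
#' curve crosses the plateau mean.
#'
#' A plateau must be detectable: the maximal trailing run (>= 2 points) of
#' tensions all within `2 * noise_sd` of their mean. Otherwise an
#' undefined-CMC error (class `memmech_undefined_cmc`) is signalled,
#' distinct from a fit failure.
#'
#' @inheritParams fit_gibbs_langmuir
#' @param method `"two-segment"` (default) or `"plateau-intersection"`.
#' @return CMC estimate in nM.
#' @examples
#' sim <- gen_adsorption(cmc = 23, seed = 2)
#' estimate_cmc(sim$data)
#' @export
estimate_cmc <- function(dataset, method = c("two-segment", "plateau-intersection"),
                         noise_sd = 0.2) {
  if (!inherits(dataset, "adsorption_data")) {
    stop_invalid_input("`dataset` must be an adsorption_data object")
  }
  method <- match.arg(method)
  conc <- dataset$concentration
  tens <- dataset$tension
  temperature <- attr(dataset, "temperature")
  n <- length(conc)

  plateau <- detect_plateau(tens, tol = 2 * noise_sd)
  if (length(plateau) < 2L) {
    stop_undefined_cmc("no micellization plateau detected (tension still declining)")
  }

  to_a <- 1000 * .R_GAS * temperature
  branch_fit <- function(idx) {
    df <- data.frame(c = conc[idx], g = tens[idx])
    minpack.lm::nlsLM(g ~ g0 - a * log1p(K * c), data = df,
                      start = list(g0 = df$g[1], a = to_a * 2e-6,
                                   K = 1 / stats::median(df$c[df$c > 0])),
                      lower = c(g0 = 1, a = 1e-8, K = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }

  if (method == "plateau-intersection") {
    g_plat <- mean(tens[plateau])
    idx <- setdiff(seq_len(n), plateau)
    if (length(idx) < 4L) stop_fit_failure("too few non-plateau points for branch fit")
    fit <- tryCatch(branch_fit(idx), error = function(e) {
      stop_fit_failure(paste("branch fit failed:", conditionMessage(e)))
    })
    p <- stats::coef(fit)
    cmc <- expm1((p["g0"] - g_plat) / p["a"]) / p["K"]
    if (!is.finite(cmc) || cmc <= 0) {
      stop_fit_failure("plateau intersection gave a non-positive concentration")
    }
    return(unname(cmc))
  }

  ## two-segment: candidate breakpoints are observed concentrations; the
  ## branch is fitted to points at or below the candidate, the plateau is
  ## the branch value at the candidate (continuity).
  cand <- seq(4L, n - 1L)
  best <- NULL
  for (j in cand) {
    idx <- seq_len(j)
    fit <- tryCatch(branch_fit(idx), error = function(e) NULL)
    if (is.null(fit)) next
    p <- stats::coef(fit)
    model <- function(cc) p["g0"] - p["a"] * log1p(p["K"] * cc)
    sse <- sum((tens[idx] - model(conc[idx]))^2) +
      sum((tens[(j + 1L):n] - model(conc[j]))^2)
    if (is.null(best) || sse < best$sse) best <- list(sse = sse, cmc = conc[j])
  }
  if (is.null(best)) stop_fit_failure("no candidate breakpoint admitted a branch fit")
  best$cmc
}
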