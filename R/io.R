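## CSV readers for the documented plain-text input formats and JSON report
## builders used by the command-line interface.

read_csv_cols <- function(path, required) {
  if (!file.exists(path)) stop_invalid_input(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop_invalid_input(sprintf("%s lacks required column(s): %s", path,
                               paste(missing, collapse = ", ")))
  }
  df
}

#' Read an adsorption dataset from CSV
#'
#' Expects columns `concentration_nM` and `surface_tension_mN_m`.
#'
#' @param path CSV file path.
#' @param temperature Absolute temperature (K), default 295.15.
#' @return An [adsorption_data()] object.
#' @export
read_adsorption_csv <- function(path, temperature = 295.15) {
  df <- read_csv_cols(path, c("concentration_nM", "surface_tension_mN_m"))
  adsorption_data(df$concentration_nM, df$surface_tension_mN_m, temperature)
}

#' Read a compression isotherm from CSV
#'
#' Expects `area_A2,pressure_mN_m`, or `trough_area_cm2,pressure_mN_m`
#' together with the amount of phosphorus spread (`spread_mol`) for the
#' area-per-molecule conversion.
#'
#' @param path CSV file path.
#' @param spread_mol Amount of phosphorus spread (mol); required with the
#'   trough-area format.
#' @param temperature Kelvin, default 295.15.
#' @return A [compression_isotherm()] object.
#' @export
read_isotherm_csv <- function(path, spread_mol = NULL, temperature = 295.15) {
  df <- read_csv_cols(path, "pressure_mN_m")
  if ("area_A2" %in% names(df)) {
    areas <- df$area_A2
  } else if ("trough_area_cm2" %in% names(df)) {
    if (is.null(spread_mol)) {
      stop_invalid_input("trough-area input needs `spread_mol`")
    }
    areas <- area_per_molecule(df$trough_area_cm2, spread_mol)
  } else {
    stop_invalid_input("need column area_A2 or trough_area_cm2")
  }
  compression_isotherm(areas, df$pressure_mN_m, temperature)
}

#' Read a FRAP trace from CSV
#'
#' Expects columns `time_s,roi,reference,background`.
#'
#' @param path CSV file path.
#' @param bleach_index Index of the first post-bleach frame.
#' @param bleach_radius Bleach-spot radius (micrometres).
#' @return A [frap_trace()] object.
#' @export
read_frap_csv <- function(path, bleach_index, bleach_radius) {
  df <- read_csv_cols(path, c("time_s", "roi", "reference", "background"))
  frap_trace(df$time_s, df$roi, df$reference, df$background,
             bleach_index, bleach_radius)
}

#' Read an aspiration step table from CSV
#'
#' Expects columns `delta_p_Pa,Lp_um,Rp_um,Rv_um`, one row per suction
#' step in acquisition order.
#'
#' @param path CSV file path.
#' @return Data frame with columns `delta_p`, `lp`, `rp`, `rv` suitable
#'   for [build_series()].
#' @export
read_aspiration_csv <- function(path) {
  df <- read_csv_cols(path, c("delta_p_Pa", "Lp_um", "Rp_um", "Rv_um"))
  data.frame(delta_p = df$delta_p_Pa, lp = df$Lp_um, rp = df$Rp_um,
             rv = df$Rv_um)
}

#' Read a densitometry lane from CSV
#'
#' Expects columns `lipid,intensity`.
#'
#' @param path CSV file path.
#' @return A [densitometry_table()] object.
#' @export
read_lane_csv <- function(path) {
  df <- read_csv_cols(path, c("lipid", "intensity"))
  densitometry_table(df$lipid, df$intensity, lane = basename(path))
}

#' Read phosphorus standards from CSV
#'
#' Expects columns `amount_umol,absorbance`.
#'
#' @param path CSV file path.
#' @return A [fit_phosphorus_curve()] calibration object.
#' @export
read_standards_csv <- function(path) {
  df <- read_csv_cols(path, c("amount_umol", "absorbance"))
  fit_phosphorus_curve(df$amount_umol, df$absorbance)
}

#' Read a GUV population from CSV
#'
#' Expects columns `vesicle_id,diameter_um` and optionally
#' `phase_separated` (0/1 or TRUE/FALSE, constant per vesicle).
#'
#' @param path CSV file path.
#' @return A [guv_population()] object.
#' @export
read_guv_csv <- function(path) {
  df <- read_csv_cols(path, c("vesicle_id", "diameter_um"))
  flags <- NULL
  if ("phase_separated" %in% names(df)) {
    per <- tapply(as.logical(df$phase_separated), df$vesicle_id, any)
    flags <- as.logical(per)
  }
  guv_population(data.frame(vesicle_id = df$vesicle_id,
                            diameter = df$diameter_um), flags)
}

## report builders (plain lists; the CLI serializes them to JSON) ----------

adsorption_report <- function(fit) {
  list(gamma0 = fit$gamma0, Gamma_inf = fit$gamma_inf_conc, K = fit$k_ads,
       uncertainties = as.list(fit$param_uncertainties),
       residual_rms = fit$residual_rms, mean_area_A2 = fit$mean_area,
       cmc_nM = fit$cmc, method = fit$cmc_method, n_points = fit$n_points)
}

bending_report <- function(fit) {
  list(kappa_kT = fit$kappa_kT, kappa_J = fit$kappa_J, slope = fit$slope,
       slope_se = fit$slope_uncertainty, sigma0_mN_m = fit$sigma0_fit,
       n_points_regime = fit$n_points, r_squared = fit$r_squared)
}

frap_report <- function(fit) {
  list(f0 = fit$f0, f_amp = fit$f_amp, plateau = fit$plateau,
       t_half_s = fit$t_half, beta = fit$beta,
       D_um2_s = fit$diffusion_coefficient,
       mobile_fraction = fit$mobile_fraction,
       residual_rms = fit$residual_rms)
}
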