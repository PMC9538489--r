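## Lipid composition, phosphorus quantification and GUV statistics ----------
##
## TLC spots are charred and quantified by densitometry; assuming a similar
## density for all lipid species, the integrated intensity of each spot is
## proportional to its mass, so percentages are % by weight relative to the
## sum of all spots. Total lipid (phosphorus) concentration comes from a
## molybdate colorimetric assay read against a KH2PO4 standard curve.

#' Build a densitometry table
#'
#' @param lipid Character vector of unique lipid-class labels.
#' @param intensity Integrated spot intensities, >= 0, at least one > 0.
#' @param lane Optional lane / extract name (metadata).
#' @return Object of class `densitometry_table`.
#' @export
densitometry_table <- function(lipid, intensity, lane = NA_character_) {
  if (length(lipid) != length(intensity)) {
    stop_invalid_input("lipid and intensity must have equal length")
  }
  if (anyDuplicated(lipid)) stop_invalid_input("lipid labels must be unique")
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop_invalid_input("intensities must be finite and >= 0")
  }
  if (all(intensity == 0)) {
    stop_invalid_input("at least one spot intensity must be positive")
  }
  out <- data.frame(lipid = as.character(lipid), intensity = intensity)
  attr(out, "lane") <- lane
  class(out) <- c("densitometry_table", "data.frame")
  out
}

#' Percent composition from spot intensities
#'
#' `percentage_i = 100 * intensity_i / sum(intensities)`.
#'
#' @param table A [densitometry_table()].
#' @return Object of class `composition_table`: data frame with columns
#'   `lipid` and `percent` (summing to 100), with attributes `basis`
#'   ("including") and `excluded` (NULL).
#' @export
percent_composition <- function(table) {
  if (!inherits(table, "densitometry_table")) {
    stop_invalid_input("`table` must be a densitometry_table object")
  }
  out <- data.frame(lipid = table$lipid,
                    percent = 100 * table$intensity / sum(table$intensity))
  attr(out, "basis") <- "including"
  attr(out, "excluded") <- NULL
  attr(out, "lane") <- attr(table, "lane")
  class(out) <- c("composition_table", "data.frame")
  out
}

#' Renormalize a composition excluding one component
#'
#' Removes the named component (e.g. cholesterol) and rescales the
#' remaining percentages to sum to 100, as in "% of total phospholipids,
#' excluding cholesterol" tabulations.
#'
#' @param composition A [percent_composition()] result.
#' @param component Label of the component to exclude.
#' @return A `composition_table` with `basis = "excluding"` and the
#'   excluded label recorded.
#' @export
renormalize_excluding <- function(composition, component) {
  if (!inherits(composition, "composition_table")) {
    stop_invalid_input("`composition` must be a composition_table object")
  }
  i <- match(component, composition$lipid)
  if (is.na(i)) stop_invalid_input(sprintf("component '%s' not present", component))
  if (nrow(composition) == 1L) {
    stop_invalid_input("cannot exclude the only component")
  }
  rest <- composition[-i, , drop = FALSE]
  s <- sum(rest$percent)
  if (s <= 0) stop_invalid_input("remaining components have zero total")
  out <- data.frame(lipid = rest$lipid, percent = 100 * rest$percent / s)
  attr(out, "basis") <- "excluding"
  attr(out, "excluded") <- component
  attr(out, "lane") <- attr(composition, "lane")
  class(out) <- c("composition_table", "data.frame")
  out
}

#' Summarize replicate lanes as mean and SEM per lipid class
#'
#' @param lanes List of [composition_table()] objects sharing the same
#'   lipid labels (replicate experiments).
#' @return Data frame with columns `lipid`, `mean_percent`, `sem`.
#' @export
summarize_lanes <- function(lanes) {
  if (!is.list(lanes) || length(lanes) < 2L ||
      !all(vapply(lanes, inherits, logical(1), "composition_table"))) {
    stop_invalid_input("`lanes` must be a list of >= 2 composition_table objects")
  }
  labels <- lanes[[1L]]$lipid
  mat <- vapply(lanes, function(l) {
    if (!identical(sort(l$lipid), sort(labels))) {
      stop_invalid_input("replicate lanes must share lipid labels")
    }
    l$percent[match(labels, l$lipid)]
  }, numeric(length(labels)))
  data.frame(lipid = labels,
             mean_percent = rowMeans(mat),
             sem = apply(mat, 1L, stats::sd) / sqrt(ncol(mat)))
}

#' Fit a phosphorus standard curve
#'
#' Ordinary least-squares line of absorbance (750 nm) on KH2PO4 amount.
#'
#' @param standard_amounts Standard amounts (micromol), >= 3 values
#'   spanning a positive range.
#' @param absorbances Measured absorbances.
#' @return Object of class `phosphorus_calibration` with `slope`,
#'   `intercept`, `r_squared` and the standards.
#' @export
fit_phosphorus_curve <- function(standard_amounts, absorbances) {
  if (length(standard_amounts) != length(absorbances)) {
    stop_invalid_input("amounts and absorbances must have equal length")
  }
  if (length(standard_amounts) < 3L || diff(range(standard_amounts)) <= 0) {
    stop_invalid_input("need >= 3 standards spanning a positive range")
  }
  fit <- stats::lm(absorbances ~ standard_amounts)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope <= 0) {
    stop_fit_failure("standard curve has non-positive slope")
  }
  out <- list(slope = slope,
              intercept = unname(stats::coef(fit)[1L]),
              r_squared = summary(fit)$r.squared,
              standard_amounts = standard_amounts,
              absorbances = absorbances)
  class(out) <- "phosphorus_calibration"
  out
}

#' Quantify phosphorus from an absorbance reading
#'
#' `amount = (A - intercept) / slope * dilution_factor`. The absorbance
#' must fall within the calibrated range extended by at most 20% of its
#' span on either side.
#'
#' @param absorbance Sample absorbance at 750 nm.
#' @param calibration A [fit_phosphorus_curve()] result.
#' @param dilution_factor Multiplicative dilution correction (default 1).
#' @return Phosphorus amount (micromol).
#' @export
quantify_phosphorus <- function(absorbance, calibration, dilution_factor = 1) {
  if (!inherits(calibration, "phosphorus_calibration")) {
    stop_invalid_input("`calibration` must be a phosphorus_calibration object")
  }
  check_scalar(dilution_factor, "dilution_factor")
  rng <- range(calibration$absorbances)
  span <- diff(rng)
  if (absorbance < rng[1L] - 0.2 * span || absorbance > rng[2L] + 0.2 * span) {
    stop_out_of_range("absorbance lies more than 20% outside the calibrated range")
  }
  (absorbance - calibration$intercept) / calibration$slope * dilution_factor
}

#' Build a GUV population
#'
#' Per-vesicle true diameters; when a measurement table with repeated
#' vesicle ids is supplied (z-stack series), the per-vesicle diameter is
#' the maximum over its measurements (the true diameter is reached at the
#' equatorial section).
#'
#' @param diameters Numeric diameters (micrometres) or a data frame with
#'   columns `vesicle_id` and `diameter`.
#' @param phase_flags Optional logical vector (one per vesicle): does the
#'   vesicle show micron-scale phase separation?
#' @return Object of class `guv_population`.
#' @export
guv_population <- function(diameters, phase_flags = NULL) {
  if (is.data.frame(diameters)) {
    if (!all(c("vesicle_id", "diameter") %in% names(diameters))) {
      stop_invalid_input("measurement table needs columns vesicle_id and diameter")
    }
    d <- tapply(diameters$diameter, diameters$vesicle_id, max)
    diameters <- as.numeric(d)
  }
  if (length(diameters) == 0L) stop_invalid_input("empty population")
  if (any(!is.finite(diameters)) || any(diameters <= 0)) {
    stop_invalid_input("diameters must be finite and > 0")
  }
  if (!is.null(phase_flags)) {
    if (length(phase_flags) != length(diameters) || !is.logical(phase_flags)) {
      stop_invalid_input("phase_flags must be logical with one entry per vesicle")
    }
  }
  out <- list(diameters = diameters, phase_flags = phase_flags)
  class(out) <- "guv_population"
  out
}

#' Size distribution of a GUV population
#'
#' @param population A [guv_population()] with at least 10 vesicles.
#' @param bin_width Histogram bin width (micrometres), default 5.
#' @return List with `breaks`, `counts`, `median`, `iqr`,
#'   `fraction_above_10um`, `n`.
#' @export
size_distribution <- function(population, bin_width = 5) {
  if (!inherits(population, "guv_population")) {
    stop_invalid_input("`population` must be a guv_population object")
  }
  d <- population$diameters
  if (length(d) < 10L) stop_invalid_input("need at least 10 vesicles")
  check_scalar(bin_width, "bin_width")
  breaks <- seq(0, (max(d) %/% bin_width + 1) * bin_width, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  list(breaks = h$breaks, counts = h$counts,
       median = stats::median(d),
       iqr = stats::IQR(d),
       fraction_above_10um = mean(d > 10),
       n = length(d))
}

## Wilson score interval for a binomial proportion
wilson_interval <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, centre - hw), upper = min(1, centre + hw))
}

#' Fraction of phase-separated vesicles
#'
#' @param population A [guv_population()] with `phase_flags` present.
#' @param conf Confidence level for the Wilson score interval (default 0.95).
#' @return List with `fraction`, `n`, `positives`, `conf_int` (Wilson).
#' @export
phase_separated_fraction <- function(population, conf = 0.95) {
  if (!inherits(population, "guv_population")) {
    stop_invalid_input("`population` must be a guv_population object")
  }
  if (is.null(population$phase_flags)) {
    stop_invalid_input("population has no phase_flags")
  }
  x <- sum(population$phase_flags)
  n <- length(population$phase_flags)
  list(fraction = x / n, n = n, positives = x,
       conf_int = wilson_interval(x, n, conf))
}
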