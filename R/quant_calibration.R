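#' Calibration series
#'
#' A set of standard solutions at known concentrations with the instrument
#' response (peak area) observed for each injection. Replicates at a level
#' are separate rows.
#'
#' @param x data frame with columns `concentration` (ng/L, > 0) and `area`;
#'   an optional `replicate` column is kept as metadata.
#' @return the validated table, class `calibration_series`.
#' @export
calibration_series <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!all(c("concentration", "area") %in% names(x))) {
    stop("calibration series needs columns 'concentration' and 'area'",
         call. = FALSE)
  }
  if (any(x$concentration <= 0)) {
    stop("calibration concentrations must be > 0", call. = FALSE)
  }
  if (length(unique(x$concentration)) < 2L) {
    stop("calibration needs >= 2 distinct concentration levels", call. = FALSE)
  }
  class(x) <- c("calibration_series", "data.frame")
  x
}

#' Fit a linear calibration curve
#'
#' Ordinary least squares of peak area on concentration (optionally
#' weighted 1/x or 1/x^2, common over wide dynamic ranges). The residual
#' standard deviation of the areas, `sigma = sqrt(RSS / (n - 2))`, feeds
#' the detection and quantification limits `LOD = 3.3 sigma / slope` and
#' `LOQ = 10 sigma / slope`. With exactly two points the fit is saturated:
#' `sigma` is 0 by convention and the fit is flagged.
#'
#' @param series a [calibration_series()] (or a bare data frame with
#'   `concentration` and `area`).
#' @param weighting `"none"` (default), `"1/x"` or `"1/x2"`.
#' @return An object of class `calibration_fit`: slope, intercept,
#'   `r_squared` (coefficient of determination), `sigma_resid`, `lod`,
#'   `loq` (ng/L), `n`, `saturated` flag and the underlying `lm` fit.
#' @examples
#' s <- calibration_series(data.frame(
#'   concentration = c(4, 20, 100, 500, 5000),
#'   area = 239 + 46.5 * c(4, 20, 100, 500, 5000)))
#' fit_calibration(s)
#' @export
fit_calibration <- function(series, weighting = c("none", "1/x", "1/x2")) {
  if (!inherits(series, "calibration_series")) series <- calibration_series(series)
  weighting <- match.arg(weighting)
  w <- switch(weighting,
              "none" = NULL,
              "1/x" = 1 / series$concentration,
              "1/x2" = 1 / series$concentration^2)
  fit <- stats::lm(area ~ concentration, data = series, weights = w)
  n <- nrow(series)
  slope <- unname(stats::coef(fit)["concentration"])
  intercept <- unname(stats::coef(fit)["(Intercept)"])
  rss <- sum(stats::residuals(fit)^2)
  saturated <- n == 2L
  sigma <- if (saturated) 0 else sqrt(rss / (n - 2))
  r2 <- stats::cor(series$concentration, series$area)^2
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r2, sigma_resid = sigma,
                 lod = if (slope > 0) lod(sigma, slope) else NA_real_,
                 loq = if (slope > 0) loq(sigma, slope) else NA_real_,
                 n = n, weighting = weighting, saturated = saturated,
                 lm = fit),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Calibration fit (n = %d%s): area = %.4g * conc + %.4g\n",
              x$n, if (x$saturated) ", saturated" else "", x$slope, x$intercept))
  cat(sprintf("  R^2 = %.6f, sigma = %.4g, LOD = %.4g ng/L, LOQ = %.4g ng/L\n",
              x$r_squared, x$sigma_resid, x$lod, x$loq))
  invisible(x)
}

#' Detection and quantification limits from a calibration
#'
#' `LOD = 3.3 sigma / p` and `LOQ = 10 sigma / p`, where `sigma` is the
#' residual standard deviation of the areas and `p` the calibration slope.
#' Their ratio is exactly 10/3.3 whatever the inputs.
#'
#' @param sigma residual standard deviation, area units (>= 0).
#' @param slope calibration slope, area per ng/L (> 0).
#' @return concentration limit, ng/L.
#' @examples
#' lod(0.43, 46.5)  # 0.0305 -> reported 0.03 ng/L
#' loq(0.43, 46.5)  # 0.0925 -> reported 0.09 ng/L
#' @export
lod <- function(sigma, slope) {
  stop_if_not_positive(sigma = sigma, .allow_zero = TRUE)
  stop_if_not_positive(slope = slope)
  3.3 * sigma / slope
}

#' @rdname lod
#' @export
loq <- function(sigma, slope) {
  stop_if_not_positive(sigma = sigma, .allow_zero = TRUE)
  stop_if_not_positive(slope = slope)
  10 * sigma / slope
}

#' Relative standard deviation
#'
#' `RSD = 100 * sd / mean` (percent), the usual repeatability /
#' reproducibility statistic; `precision_check()` applies the conventional
#' < 10 % acceptance limit.
#'
#' @param values numeric vector of >= 2 replicate measurements with
#'   non-zero mean.
#' @return RSD in percent.
#' @examples
#' rsd(c(9, 10, 11))  # 10
#' @export
rsd <- function(values) {
  if (length(values) < 2L) stop("rsd needs >= 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("rsd undefined for zero mean", call. = FALSE)
  100 * stats::sd(values) / m
}

#' @rdname rsd
#' @param limit acceptance limit, percent.
#' @export
precision_check <- function(values, limit = 10) {
  rsd(values) < limit
}

#' Predict the instrument response at a concentration
#'
#' @param object a `calibration_fit`.
#' @param concentration concentration(s), ng/L.
#' @param ... unused.
#' @return predicted peak area(s).
#' @export
predict.calibration_fit <- function(object, concentration, ...) {
  object$intercept + object$slope * concentration
}

#' Back-calculate a sample concentration from its peak area
#'
#' Inverts the calibration line, `c = (area - intercept) / slope`, and
#' classifies the result against the detection limits: below LOD the
#' analyte is reported `not_detected`, between LOD and LOQ
#' `detected_not_quantifiable`, at or above LOQ `quantified`.
#'
#' @param area peak area(s).
#' @param fit a `calibration_fit` with positive slope.
#' @param sample_id optional identifier(s), recycled.
#' @param analyte analyte name.
#' @return data frame of class `measured_concentration`: `sample_id`,
#'   `analyte`, `area`, `concentration` (ng/L), `status`.
#' @examples
#' s <- calibration_series(data.frame(
#'   concentration = c(4, 20, 100, 500, 5000),
#'   area = 239 + 46.5 * c(4, 20, 100, 500, 5000)))
#' quantify(1748, fit_calibration(s))  # 32.45 ng/L, quantified
#' @export
quantify <- function(area, fit, sample_id = NA_character_,
                     analyte = NA_character_) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$slope <= 0) stop("calibration slope must be > 0", call. = FALSE)
  conc <- (area - fit$intercept) / fit$slope
  status <- ifelse(conc < fit$lod, "not_detected",
                   ifelse(conc < fit$loq, "detected_not_quantifiable",
                          "quantified"))
  out <- data.frame(sample_id = rep_len(sample_id, length(area)),
                    analyte = analyte, area = area,
                    concentration = conc, status = status,
                    stringsAsFactors = FALSE)
  class(out) <- c("measured_concentration", "data.frame")
  out
}

#' Compare a measured concentration with prediction and no-effect level
#'
#' Confronts a measured environmental concentration (MEC) with the
#' model-predicted surface-water concentration and with the water PNEC,
#' after unit harmonisation. `measured_below_predicted` reports whether the
#' model was conservative; `measured_risk_acceptable` whether the
#' measurement-based risk quotient stays below 1.
#'
#' @param mec measured concentration.
#' @param pec_sw predicted surface-water concentration.
#' @param pnec_water water no-effect concentration.
#' @param mec_unit,pec_unit,pnec_unit units (per-volume).
#' @return list with `mec_pec_ratio`, `mec_pnec_ratio`,
#'   `measured_below_predicted`, `measured_risk_acceptable`.
#' @examples
#' mec_compare(0.032, 37.66, 1)  # ratios 8.5e-4 and 3.2e-5
#' @export
mec_compare <- function(mec, pec_sw, pnec_water,
                        mec_unit = "ug/L", pec_unit = "ug/L",
                        pnec_unit = "mg/L") {
  stop_if_not_positive(mec = mec, .allow_zero = TRUE)
  stop_if_not_positive(pec_sw = pec_sw, pnec_water = pnec_water)
  mec_c <- convert_unit(mec, mec_unit, "ug/L")
  pec_c <- convert_unit(pec_sw, pec_unit, "ug/L")
  pnec_c <- convert_unit(pnec_water, pnec_unit, "ug/L")
  list(mec_pec_ratio = mec_c / pec_c,
       mec_pnec_ratio = mec_c / pnec_c,
       measured_below_predicted = mec_c < pec_c,
       measured_risk_acceptable = mec_c / pnec_c < 1)
}
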