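#' Concentration unit handling
#'
#' The assessment mixes mass-per-volume units (waters: ng/L, ug/L, mg/L) and
#' mass-per-dry-mass units (soil, sediment: ug/kg, mg/kg). Conversion within a
#' dimension is a power-of-ten rescale; conversion across dimensions is
#' refused rather than coerced.
#'
#' @param value numeric vector of concentrations.
#' @param from,to unit strings; the micro sign and `"u"` are interchangeable.
#' @return `convert_unit()` returns `value` rescaled to `to`.
#' @examples
#' convert_unit(37.66, "ug/L", "mg/L")
#' @export
convert_unit <- function(value, from, to) {
  from <- rep_len(normalize_unit(from), length(value))
  to <- rep_len(normalize_unit(to), length(value))
  bad <- unit_dimension(from) != unit_dimension(to)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("cannot convert '%s' to '%s': incompatible dimensions",
                 from[i], to[i]), call. = FALSE)
  }
  value * unit_factor(from) / unit_factor(to)
}

# factors to the canonical unit of each dimension (ug/L resp. ug/kg)
.unit_factors <- c(
  "ng/L" = 1e-3, "ug/L" = 1, "mg/L" = 1e3, "g/L" = 1e6,
  "ug/kg" = 1, "mg/kg" = 1e3, "g/kg" = 1e6
)

#' @rdname convert_unit
#' @export
normalize_unit <- function(unit) {
  u <- gsub("µ|μ", "u", trimws(unit))
  bad <- !(u %in% names(.unit_factors))
  if (any(bad)) {
    stop(sprintf("unknown concentration unit(s): %s",
                 paste(sQuote(unique(unit[bad])), collapse = ", ")), call. = FALSE)
  }
  u
}

unit_factor <- function(unit) unname(.unit_factors[unit])

#' @rdname convert_unit
#' @export
unit_dimension <- function(unit) {
  unit <- normalize_unit(unit)
  ifelse(grepl("/L$", unit), "water", "solid")
}

stop_if_not_positive <- function(..., .allow_zero = FALSE) {
  vals <- list(...)
  nms <- names(vals)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      stop(sprintf("'%s' must be a single finite number", nms[i]), call. = FALSE)
    }
    ok <- if (.allow_zero) v >= 0 else v > 0
    if (!ok) {
      stop(sprintf("'%s' must be %s (got %g)", nms[i],
                   if (.allow_zero) "non-negative" else "strictly positive", v),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
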