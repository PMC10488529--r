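#' Ecotoxicity endpoint table
#'
#' Validates a table of experimental toxicity endpoints. Each row is one
#' test result: the environmental compartment it protects, the test
#' organism, the endpoint type (chronic NOEC or acute EC50/LC50), the
#' concentration with its unit, and the assessment factor (AF) dividing the
#' endpoint down to an ecosystem no-effect level. When `assessment_factor`
#' is missing it is filled from the conventional ladder: 10 for a chronic
#' NOEC, 1000 for a single acute EC50/LC50.
#'
#' @param x data frame with columns `compartment`
#'   (water/microorganism/soil/sediment), `organism`, `endpoint_type`
#'   (NOEC/EC50/LC50), `value` (> 0), `unit` (mg/L for water and
#'   microorganism, mg/kg for soil and sediment) and optionally
#'   `assessment_factor` (integer >= 1).
#' @return the validated table, class `ecotox_endpoints`.
#' @examples
#' ecotox_endpoints(data.frame(
#'   compartment = "water", organism = "algae", endpoint_type = "NOEC",
#'   value = 10, unit = "mg/L", assessment_factor = 10))
#' @export
ecotox_endpoints <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  req <- c("compartment", "organism", "endpoint_type", "value", "unit")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    stop("endpoint table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ok_comp <- c("water", "microorganism", "soil", "sediment")
  bad <- !(x$compartment %in% ok_comp)
  if (any(bad)) {
    stop("unknown compartment(s): ",
         paste(unique(x$compartment[bad]), collapse = ", "), call. = FALSE)
  }
  ok_type <- c("NOEC", "EC50", "LC50")
  if (any(!(x$endpoint_type %in% ok_type))) {
    stop("endpoint_type must be one of ", paste(ok_type, collapse = "/"),
         call. = FALSE)
  }
  if (any(x$value <= 0)) stop("endpoint values must be > 0", call. = FALSE)
  x$unit <- normalize_unit(x$unit)
  want_dim <- ifelse(x$compartment %in% c("water", "microorganism"),
                     "water", "solid")
  got_dim <- unit_dimension(x$unit)
  if (any(got_dim != want_dim)) {
    i <- which(got_dim != want_dim)[1]
    stop(sprintf("row %d: unit '%s' does not match compartment '%s'",
                 i, x$unit[i], x$compartment[i]), call. = FALSE)
  }
  if (!("assessment_factor" %in% names(x))) x$assessment_factor <- NA_real_
  fill <- is.na(x$assessment_factor)
  x$assessment_factor[fill] <- ifelse(x$endpoint_type[fill] == "NOEC", 10, 1000)
  if (any(x$assessment_factor < 1 |
          x$assessment_factor != round(x$assessment_factor))) {
    stop("assessment_factor must be an integer >= 1", call. = FALSE)
  }
  class(x) <- c("ecotox_endpoints", "data.frame")
  x
}

#' Assessment-factor PNEC for one compartment
#'
#' Divides every endpoint of the compartment by its assessment factor and
#' takes the minimum: the most protective experimentally anchored no-effect
#' concentration. Values are harmonised to mg/L (water, microorganism) or
#' mg/kg (soil, sediment) before comparison.
#'
#' @param endpoints an [ecotox_endpoints()] table.
#' @param compartment one of water, microorganism, soil, sediment.
#' @return list with `value` (mg/L or mg/kg), `unit`, `organism` and
#'   `endpoint_type` of the driving row.
#' @examples
#' eps <- ecotox_endpoints(data.frame(
#'   compartment = "water", organism = "algae", endpoint_type = "NOEC",
#'   value = 10, unit = "mg/L", assessment_factor = 10))
#' pnec_af(eps, "water")$value  # 1 mg/L
#' @export
pnec_af <- function(endpoints, compartment) {
  stopifnot(inherits(endpoints, "ecotox_endpoints"))
  rows <- endpoints[endpoints$compartment == compartment, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop(sprintf("no AF-based PNEC: no ecotoxicity endpoint for compartment '%s'",
                 compartment), call. = FALSE)
  }
  target <- if (compartment %in% c("water", "microorganism")) "mg/L" else "mg/kg"
  cand <- convert_unit(rows$value, rows$unit, target) / rows$assessment_factor
  i <- which.min(cand)
  list(value = cand[i], unit = target,
       organism = rows$organism[i], endpoint_type = rows$endpoint_type[i])
}

#' Equilibrium-partitioning PNEC for soil
#'
#' Translates the water no-effect concentration onto bulk soil through the
#' soil-water partition factor: `PNEC_soil = f * PNEC_water` with
#' `f = 0.1176 + 0.01764 * Koc` (or the substance override).
#'
#' @param substance a [substance_properties()].
#' @param pnec_water water no-effect concentration, mg/L (> 0).
#' @return soil no-effect concentration, mg/kg.
#' @examples
#' pnec_ep_soil(substance_properties("x", koc = 421), 1)  # 7.544
#' @export
pnec_ep_soil <- function(substance, pnec_water) {
  stop_if_not_positive(pnec_water = pnec_water)
  partition_factor(substance) * pnec_water
}

#' Equilibrium-partitioning PNEC for sediment
#'
#' `PNEC_sed = (0.783 + 0.0217 * Koc) * PNEC_water`. Unlike the soil route
#' this factor is always computed from Koc; the partition-factor override
#' does not apply here.
#'
#' @inheritParams pnec_ep_soil
#' @return sediment no-effect concentration, mg/kg.
#' @examples
#' pnec_ep_sediment(substance_properties("x", koc = 421), 1)  # 9.9187
#' @export
pnec_ep_sediment <- function(substance, pnec_water) {
  stop_if_not_positive(pnec_water = pnec_water)
  sediment_accumulation_factor(substance) * pnec_water
}

#' Select the PNEC used for risk
#'
#' When both the assessment-factor and the partition-equilibrium routes
#' yield a candidate, the lower (more protective) value is used. When a
#' compartment has no experimental endpoint the equilibrium value stands
#' alone.
#'
#' @param af_value AF-route candidate, or `NULL` if the compartment has no
#'   experimental endpoint.
#' @param ep_value EP-route candidate, or `NULL` where equilibrium
#'   partitioning does not apply.
#' @param compartment compartment name, carried into the result.
#' @param unit unit of the candidates.
#' @return An object of class `pnec_result` with fields `compartment`,
#'   `af_value`, `ep_value`, `selected` and `method_used`
#'   (`"AF"`, `"EP"` or `"min(AF,EP)"`).
#' @examples
#' select_pnec(20, 7.69, "soil", "mg/kg")$selected  # 7.69
#' @export
select_pnec <- function(af_value = NULL, ep_value = NULL, compartment,
                        unit = "mg/kg") {
  if (is.null(af_value) && is.null(ep_value)) {
    stop(sprintf("no PNEC candidate for compartment '%s'", compartment),
         call. = FALSE)
  }
  if (is.null(ep_value)) {
    sel <- af_value; method <- "AF"
  } else if (is.null(af_value)) {
    sel <- ep_value; method <- "EP"
  } else {
    sel <- min(af_value, ep_value); method <- "min(AF,EP)"
  }
  if (sel <= 0) stop("selected PNEC must be > 0", call. = FALSE)
  structure(list(compartment = compartment,
                 af_value = af_value, ep_value = ep_value,
                 selected = sel, method_used = method, unit = unit),
            class = "pnec_result")
}

#' @export
print.pnec_result <- function(x, ...) {
  fmt <- function(v) if (is.null(v)) "-" else sprintf("%.4g", v)
  cat(sprintf("PNEC %-13s %s %s  [AF %s | EP %s, rule %s]\n",
              x$compartment, fmt(x$selected), x$unit,
              fmt(x$af_value), fmt(x$ep_value), x$method_used))
  invisible(x)
}

#' Derive the PNEC set used by the decision tree
#'
#' Water and microorganism PNECs come from the assessment-factor route
#' (water is mandatory: groundwater and surface-water risk need it). Soil
#' and sediment each take the minimum of their AF route (when endpoints
#' exist) and the equilibrium-partitioning route anchored on the water
#' PNEC; with no experimental endpoint the EP value is used alone.
#'
#' @param endpoints an [ecotox_endpoints()] table; must contain at least one
#'   water endpoint.
#' @param substance a [substance_properties()].
#' @return named list of [select_pnec()] results for `water`,
#'   `microorganism` (when endpoints exist), `soil` and `sediment`.
#' @export
derive_pnecs <- function(endpoints, substance) {
  stopifnot(inherits(endpoints, "ecotox_endpoints"))
  has <- function(comp) any(endpoints$compartment == comp)
  if (!has("water")) {
    stop("no ecotoxicity endpoint for compartment 'water'; a water PNEC is required",
         call. = FALSE)
  }
  water_af <- pnec_af(endpoints, "water")
  out <- list(water = select_pnec(af_value = water_af$value, ep_value = NULL,
                                  compartment = "water", unit = "mg/L"))
  if (has("microorganism")) {
    out$microorganism <- select_pnec(
      af_value = pnec_af(endpoints, "microorganism")$value, ep_value = NULL,
      compartment = "microorganism", unit = "mg/L")
  }
  pw <- out$water$selected
  out$soil <- select_pnec(
    af_value = if (has("soil")) pnec_af(endpoints, "soil")$value else NULL,
    ep_value = pnec_ep_soil(substance, pw),
    compartment = "soil", unit = "mg/kg")
  out$sediment <- select_pnec(
    af_value = if (has("sediment")) pnec_af(endpoints, "sediment")$value else NULL,
    ep_value = pnec_ep_sediment(substance, pw),
    compartment = "sediment", unit = "mg/kg")
  out
}
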