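#' File I/O for scenarios, substances, endpoint tables and reports
#'
#' Hand-edited configuration travels as JSON with a `format_version` field;
#' tabular data as CSV. Readers validate strictly and refuse rather than
#' coerce on schema or unit violations; `read(write(x))` round-trips.
#'
#' @param scenario a [product_scenario()].
#' @param path file path.
#' @param sediment_override optional stored worst-case sediment PEC, ug/kg,
#'   carried in the scenario file.
#' @return readers return the validated object; writers return the path
#'   invisibly.
#' @name vetera_io
NULL

.format_version <- "1.0"

check_format_version <- function(obj, path) {
  if (is.null(obj$format_version)) {
    stop(sprintf("%s: missing 'format_version' field", path), call. = FALSE)
  }
  if (!identical(as.character(obj$format_version), .format_version)) {
    stop(sprintf("%s: unsupported format_version '%s' (expected %s)",
                 path, obj$format_version, .format_version), call. = FALSE)
  }
}

#' @rdname vetera_io
#' @export
write_scenario <- function(scenario, path, sediment_override = NULL) {
  stopifnot(inherits(scenario, "product_scenario"))
  obj <- list(format_version = .format_version,
              name = scenario$name, ai_content = scenario$ai_content,
              route = scenario$route, regimens = scenario$regimens)
  if (!is.null(sediment_override)) obj$sediment_override <- sediment_override
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname vetera_io
#' @export
read_scenario <- function(path) {
  obj <- jsonlite::fromJSON(path)
  check_format_version(obj, path)
  sc <- product_scenario(name = obj$name, ai_content = obj$ai_content,
                         regimens = obj$regimens, route = obj$route)
  attr(sc, "sediment_override") <- obj$sediment_override
  sc
}

#' @rdname vetera_io
#' @param substance a [substance_properties()].
#' @export
write_substance <- function(substance, path) {
  stopifnot(inherits(substance, "substance_properties"))
  obj <- c(list(format_version = .format_version),
           unclass(substance))
  obj <- obj[!vapply(obj, is.null, logical(1))]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname vetera_io
#' @export
read_substance <- function(path) {
  obj <- jsonlite::fromJSON(path)
  check_format_version(obj, path)
  substance_properties(
    name = obj$name,
    molar_mass = obj$molar_mass %||% NA_real_,
    solubility = obj$solubility %||% NA_real_,
    vapor_pressure = obj$vapor_pressure %||% NA_real_,
    koc = obj$koc,
    partition_factor_override = obj$partition_factor_override)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname vetera_io
#' @export
read_endpoints <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  tryCatch(ecotox_endpoints(x), error = function(e) {
    stop(sprintf("%s: %s", path, conditionMessage(e)), call. = FALSE)
  })
}

#' @rdname vetera_io
#' @export
read_calibration <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  tryCatch(calibration_series(x), error = function(e) {
    stop(sprintf("%s: %s", path, conditionMessage(e)), call. = FALSE)
  })
}

#' @rdname vetera_io
#' @export
read_mec <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "area")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    stop(sprintf("%s: MEC table lacks column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  x
}

#' @rdname vetera_io
#' @param assessment an `era_assessment` from [run_assessment()].
#' @export
write_report <- function(assessment, path) {
  stopifnot(inherits(assessment, "era_assessment"))
  obj <- list(
    format_version = .format_version,
    conclusion = assessment$conclusion,
    phase1 = assessment$phase1,
    worst_case_species = if (!is.null(assessment$pec)) {
      attr(assessment$pec, "worst_case_species")
    },
    partition_factor = if (!is.null(assessment$pec)) {
      attr(assessment$pec, "partition_factor")
    },
    pec = if (!is.null(assessment$pec)) as.data.frame(assessment$pec),
    pnec = if (!is.null(assessment$pnec)) {
      lapply(assessment$pnec, function(p) {
        list(compartment = p$compartment, af_value = p$af_value,
             ep_value = p$ep_value, selected = p$selected,
             method_used = p$method_used, unit = p$unit)
      })
    },
    risk = assessment$risk,
    refined = assessment$refined,
    trace = assessment$trace)
  obj <- obj[!vapply(obj, is.null, logical(1))]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Render the headline tables of an assessment
#'
#' Human-readable counterpart of [write_report()]: the worst-case PEC
#' table, the PNEC table and the risk-quotient table, rounded the way such
#' reports conventionally print (2 decimals for concentrations, 3 for risk
#' quotients). Rounding happens here only; stored values keep full
#' precision.
#'
#' @param assessment an `era_assessment`.
#' @return named list of data frames (`pec`, `pnec`, `risk`).
#' @export
render_tables <- function(assessment) {
  stopifnot(inherits(assessment, "era_assessment"))
  if (assessment$conclusion == "phase1_stop") {
    p1 <- assessment$phase1
    p1$pec_soil <- round(p1$pec_soil, 2)
    return(list(phase1 = p1))
  }
  worst <- attr(assessment$pec, "worst_case_species")
  pec <- as.data.frame(assessment$pec)
  pec <- pec[pec$species == worst, c("compartment", "value", "unit")]
  pec$value <- round(pec$value, 2)
  pnec <- do.call(rbind, lapply(assessment$pnec, function(p) {
    data.frame(compartment = p$compartment,
               af_value = round(p$af_value %||% NA_real_, 2),
               ep_value = round(p$ep_value %||% NA_real_, 2),
               selected = round(p$selected, 2), unit = p$unit,
               method = p$method_used, stringsAsFactors = FALSE)
  }))
  rownames(pnec) <- NULL
  risk <- assessment$headline[, c("compartment", "pec", "pec_unit",
                                  "pnec", "pnec_unit", "R")]
  risk$pec <- round(risk$pec, 2)
  risk$R <- round(risk$R, 3)
  rownames(risk) <- NULL
  list(pec = pec, pnec = pnec, risk = risk)
}

#' @rdname vetera_io
#' @param registry a [husbandry_registry()].
#' @export
write_husbandry_registry <- function(registry, path) {
  jsonlite::write_json(as.data.frame(registry), path, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
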