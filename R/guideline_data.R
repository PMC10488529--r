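#' Phase I soil scenario constants
#'
#' Fixed parameters of the intensively-reared-livestock exposure scenario:
#' manure is applied to arable land up to the EU nitrogen ceiling and the
#' residue is mixed into the plough layer. Defaults are the guideline worst
#' case: 170 kg N/ha/year, dry bulk density 1500 kg/m3, a 5 cm incorporation
#' depth for the Phase I soil concentration, a 20 cm layer for the
#' groundwater pathway, 1 ha = 10000 m2, and a 3-fold dilution of pore water
#' into surface water.
#'
#' @param nitrogen_limit areal nitrogen ceiling, kg N/ha.
#' @param bulk_density dry soil bulk density, kg/m3.
#' @param mixing_depth_phase1 shallow incorporation depth, m.
#' @param mixing_depth_deep deep (groundwater-relevant) mixing depth, m;
#'   must exceed `mixing_depth_phase1`.
#' @param hectare_area reference area, m2.
#' @param surface_water_dilution dimensionless pore-water to surface-water
#'   dilution factor.
#' @return An object of class `soil_scenario`.
#' @examples
#' soil_scenario()
#' @export
soil_scenario <- function(nitrogen_limit = 170,
                          bulk_density = 1500,
                          mixing_depth_phase1 = 0.05,
                          mixing_depth_deep = 0.20,
                          hectare_area = 10000,
                          surface_water_dilution = 3) {
  stop_if_not_positive(nitrogen_limit = nitrogen_limit,
                       bulk_density = bulk_density,
                       mixing_depth_phase1 = mixing_depth_phase1,
                       mixing_depth_deep = mixing_depth_deep,
                       hectare_area = hectare_area,
                       surface_water_dilution = surface_water_dilution)
  if (mixing_depth_deep <= mixing_depth_phase1) {
    stop("'mixing_depth_deep' must exceed 'mixing_depth_phase1'", call. = FALSE)
  }
  structure(
    list(nitrogen_limit = nitrogen_limit,
         bulk_density = bulk_density,
         mixing_depth_phase1 = mixing_depth_phase1,
         mixing_depth_deep = mixing_depth_deep,
         hectare_area = hectare_area,
         surface_water_dilution = surface_water_dilution),
    class = "soil_scenario")
}

#' @export
print.soil_scenario <- function(x, ...) {
  cat("Phase I soil scenario\n")
  cat(sprintf("  nitrogen limit:        %g kg N/ha\n", x$nitrogen_limit))
  cat(sprintf("  bulk density:          %g kg/m3\n", x$bulk_density))
  cat(sprintf("  mixing depths:         %g m (phase I) / %g m (deep)\n",
              x$mixing_depth_phase1, x$mixing_depth_deep))
  cat(sprintf("  surface-water dilution: %g\n", x$surface_water_dilution))
  invisible(x)
}

# Composite husbandry factors H [kg bw x production cycles / kg N excreted
# per place-year]. H collapses the guideline's animal body weight, cycles
# per year and nitrogen excretion into one scalar so that
#   PECsoil = D * Ad * Fh * H * lrN * 1000 / (rho_b * A * d).
# The shipped values are back-derived from published worst-case soil PECs
# for a 250 mg/g penicillin G product (see derive_husbandry_factor()).
.builtin_husbandry <- data.frame(
  species = c("piglet", "chicken", "turkey"),
  composite_factor_H = c(38.3329412, 39.1301471, 19.5),
  fraction_treated = c(1, 1, 1),
  provenance = c(
    "back-derived from worst-case PECsoil 868.88 ug/kg (D=25, Ad=4, Fh=1)",
    "back-derived from worst-case PECsoil 354.78 ug/kg (D=10, Ad=4, Fh=1)",
    "back-derived from worst-case PECsoil 176.8 ug/kg (D=10, Ad=4, Fh=1)"),
  stringsAsFactors = FALSE
)

#' Husbandry defaults registry
#'
#' Per-species husbandry parameters used by the Phase I soil exposure
#' calculation, keyed by species. Each row carries the composite factor `H`
#' (kg body weight x production cycles per kg nitrogen excreted per
#' place-year) and the default fraction of the herd treated `Fh`. The
#' built-in registry covers the shipped piglet/chicken/turkey example; users
#' assessing other species supply overrides, either as a ready-made `H` via
#' [husbandry_override()] or as the body-weight/cycles/excretion triple via
#' [composite_husbandry_factor()].
#'
#' @param overrides optional data frame with columns `species`,
#'   `composite_factor_H` and optionally `fraction_treated`, `provenance`;
#'   merged over the built-ins by species key.
#' @param file optional path to a JSON registry (as written by
#'   [write_husbandry_registry()]); read and merged after `overrides`.
#' @return A data frame of class `husbandry_registry`.
#' @examples
#' husbandry_registry()
#' get_husbandry_defaults("piglet")
#' @export
husbandry_registry <- function(overrides = NULL, file = NULL) {
  reg <- .builtin_husbandry
  merge_one <- function(reg, extra) {
    extra <- validate_husbandry(extra)
    keep <- !(reg$species %in% extra$species)
    rbind(reg[keep, , drop = FALSE], extra)
  }
  if (!is.null(overrides)) reg <- merge_one(reg, overrides)
  if (!is.null(file)) {
    extra <- as.data.frame(jsonlite::fromJSON(file), stringsAsFactors = FALSE)
    reg <- merge_one(reg, extra)
  }
  rownames(reg) <- NULL
  class(reg) <- c("husbandry_registry", "data.frame")
  reg
}

validate_husbandry <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  req <- c("species", "composite_factor_H")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    stop("husbandry override lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(x$species)) {
    stop("duplicate species keys in husbandry override", call. = FALSE)
  }
  if (!("fraction_treated" %in% names(x))) x$fraction_treated <- 1
  if (!("provenance" %in% names(x))) x$provenance <- "user override"
  if (any(x$composite_factor_H <= 0)) {
    stop("composite_factor_H must be strictly positive", call. = FALSE)
  }
  if (any(x$fraction_treated <= 0 | x$fraction_treated > 1)) {
    stop("fraction_treated must lie in (0, 1]", call. = FALSE)
  }
  x[c("species", "composite_factor_H", "fraction_treated", "provenance")]
}

#' @rdname husbandry_registry
#' @param species species identifier, e.g. `"piglet"`.
#' @param registry a registry from [husbandry_registry()].
#' @export
get_husbandry_defaults <- function(species, registry = husbandry_registry()) {
  stopifnot(is.character(species), length(species) == 1L)
  hit <- which(registry$species == species)
  if (length(hit) != 1L) {
    stop(sprintf(
      "no husbandry defaults for species '%s'; supply an override (see ?husbandry_registry)",
      species), call. = FALSE)
  }
  row <- registry[hit, , drop = FALSE]
  structure(
    list(species = row$species,
         composite_factor_H = row$composite_factor_H,
         fraction_treated = row$fraction_treated,
         provenance = row$provenance),
    class = "husbandry_defaults")
}

#' @export
print.husbandry_defaults <- function(x, ...) {
  cat(sprintf("Husbandry defaults for '%s': H = %.4f, Fh = %g\n  (%s)\n",
              x$species, x$composite_factor_H, x$fraction_treated, x$provenance))
  invisible(x)
}

#' @rdname husbandry_registry
#' @param composite_factor_H composite factor, kg bw x cycles per kg N.
#' @param fraction_treated default fraction of the herd treated, in (0, 1].
#' @param provenance free-text note on where the value comes from.
#' @export
husbandry_override <- function(species, composite_factor_H,
                               fraction_treated = 1,
                               provenance = "user override") {
  validate_husbandry(data.frame(
    species = species, composite_factor_H = composite_factor_H,
    fraction_treated = fraction_treated, provenance = provenance,
    stringsAsFactors = FALSE))
}

#' Build or recover the composite husbandry factor
#'
#' `composite_husbandry_factor()` combines the guideline triple — average
#' body weight of the treated animal, number of production cycles per
#' place-year, and nitrogen excreted per place-year — into the single
#' scalar `H = BW * Ncycles / Ny` used by the Phase I formula.
#'
#' `derive_husbandry_factor()` inverts the Phase I formula: given a known
#' soil PEC and the dosing regimen, it returns the `H` that reproduces it.
#' This is how the shipped piglet/chicken/turkey factors were obtained from
#' published worst-case values.
#'
#' @param body_weight average body weight, kg.
#' @param cycles_per_year production cycles per place-year.
#' @param n_excreted_per_place_year nitrogen excreted per place-year, kg N.
#' @return the composite factor `H`, kg bw x cycles per kg N.
#' @examples
#' derive_husbandry_factor(868.88, dose = 25, duration = 4)
#' @export
composite_husbandry_factor <- function(body_weight, cycles_per_year,
                                       n_excreted_per_place_year) {
  stop_if_not_positive(body_weight = body_weight,
                       cycles_per_year = cycles_per_year,
                       n_excreted_per_place_year = n_excreted_per_place_year)
  body_weight * cycles_per_year / n_excreted_per_place_year
}

#' @rdname composite_husbandry_factor
#' @param pec_soil known Phase I soil concentration, ug/kg.
#' @param dose daily dose, mg/kg bw/day.
#' @param duration treatment duration, days.
#' @param fraction_treated fraction of the herd treated, in (0, 1].
#' @param soil a [soil_scenario()].
#' @export
derive_husbandry_factor <- function(pec_soil, dose, duration,
                                    fraction_treated = 1,
                                    soil = soil_scenario()) {
  stop_if_not_positive(pec_soil = pec_soil, dose = dose, duration = duration,
                       fraction_treated = fraction_treated)
  pec_soil * soil$bulk_density * soil$hectare_area * soil$mixing_depth_phase1 /
    (dose * duration * fraction_treated * soil$nitrogen_limit * 1000)
}
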