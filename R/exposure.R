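#' Product scenario: a veterinary product and its dosing regimens
#'
#' @param name product name.
#' @param ai_content active-ingredient content of the formulation, mg/g.
#' @param regimens data frame with columns `species`, `dose` (mg active
#'   ingredient per kg body weight per day) and `duration` (whole days >= 1);
#'   an optional `fraction_treated` column overrides the registry default.
#' @param route administration route, free text.
#' @return An object of class `product_scenario`.
#' @examples
#' product_scenario("example", 250,
#'   data.frame(species = "piglet", dose = 25, duration = 4))
#' @export
product_scenario <- function(name, ai_content, regimens,
                             route = "oral, drinking water") {
  stop_if_not_positive(ai_content = ai_content)
  regimens <- as.data.frame(regimens, stringsAsFactors = FALSE)
  req <- c("species", "dose", "duration")
  if (!all(req %in% names(regimens)) || nrow(regimens) < 1L) {
    stop("'regimens' needs >= 1 row with columns species, dose, duration",
         call. = FALSE)
  }
  if (anyDuplicated(regimens$species)) {
    stop("duplicate species in regimens", call. = FALSE)
  }
  if (any(regimens$dose < 0)) stop("dose must be >= 0", call. = FALSE)
  if (any(regimens$duration < 1 | regimens$duration != round(regimens$duration))) {
    stop("duration must be an integer number of days >= 1", call. = FALSE)
  }
  if ("fraction_treated" %in% names(regimens)) {
    ft <- regimens$fraction_treated
    if (any(!is.na(ft) & (ft <= 0 | ft > 1))) {
      stop("fraction_treated must lie in (0, 1]", call. = FALSE)
    }
  }
  structure(list(name = name, ai_content = ai_content,
                 regimens = regimens, route = route),
            class = "product_scenario")
}

#' @export
print.product_scenario <- function(x, ...) {
  cat(sprintf("Product scenario '%s' (%g mg/g active ingredient, %s)\n",
              x$name, x$ai_content, x$route))
  print(x$regimens, row.names = FALSE)
  invisible(x)
}

#' Substance properties of the active ingredient
#'
#' Physico-chemical parameters. Only `koc` enters the Tier A partitioning
#' equations; molar mass, solubility and vapor pressure are carried as
#' metadata and reported but unused by the reproduced calculation chain.
#' `partition_factor_override`, when set, replaces the computed soil-water
#' partition factor verbatim in every soil-water partitioning step (used to
#' reproduce published chains whose printed factor is inconsistent with the
#' printed Koc).
#'
#' @param name substance name.
#' @param molar_mass g/mol (metadata).
#' @param solubility water solubility, mg/L (metadata).
#' @param vapor_pressure vapor pressure in the source's stated units
#'   (metadata).
#' @param koc organic-carbon-water partition coefficient, L/kg.
#' @param partition_factor_override optional soil-water partition factor,
#'   L/kg, used verbatim when present.
#' @return An object of class `substance_properties`.
#' @examples
#' substance_properties("penicillin G", 372.48, 307, 2370, koc = 421)
#' @export
substance_properties <- function(name, molar_mass = NA_real_,
                                 solubility = NA_real_,
                                 vapor_pressure = NA_real_,
                                 koc, partition_factor_override = NULL) {
  stop_if_not_positive(koc = koc, .allow_zero = TRUE)
  if (!is.null(partition_factor_override)) {
    stop_if_not_positive(partition_factor_override = partition_factor_override)
  }
  structure(list(name = name, molar_mass = molar_mass,
                 solubility = solubility, vapor_pressure = vapor_pressure,
                 koc = koc,
                 partition_factor_override = partition_factor_override),
            class = "substance_properties")
}

#' @export
print.substance_properties <- function(x, ...) {
  cat(sprintf("Substance '%s': MW %g g/mol, SOL %g mg/L, VP %g, Koc %g L/kg\n",
              x$name, x$molar_mass, x$solubility, x$vapor_pressure, x$koc))
  if (!is.null(x$partition_factor_override)) {
    cat(sprintf("  soil-water partition factor override: %g L/kg\n",
                x$partition_factor_override))
  }
  invisible(x)
}

#' Phase I total-residue soil concentration
#'
#' Worst-case soil exposure assuming the whole administered dose is excreted
#' unmetabolized into manure and the manure is spread up to the nitrogen
#' ceiling, then mixed into the shallow plough layer:
#'
#' \deqn{PEC_{soil} = \frac{D \cdot A_d \cdot F_h \cdot H \cdot lr_N \cdot 1000}
#'   {\rho_b \cdot A \cdot d}}
#'
#' with `D` the daily dose (mg/kg bw/day), `Ad` the treatment duration
#' (days), `Fh` the fraction of the herd treated, `H` the composite
#' husbandry factor, `lrN` the nitrogen ceiling (kg N/ha), `rho_b` the bulk
#' density (kg/m3), `A` the hectare area (m2) and `d` the mixing depth (m).
#' The factor 1000 converts mg/kg to ug/kg.
#'
#' @param dose daily dose `D`, mg/kg bw/day (>= 0).
#' @param duration treatment duration `Ad`, days.
#' @param husbandry a `husbandry_defaults` object or a bare composite
#'   factor `H`.
#' @param soil a [soil_scenario()].
#' @param fraction_treated `Fh` in (0, 1]; defaults to the registry value
#'   when `husbandry` is a `husbandry_defaults`, else 1.
#' @return soil concentration, ug/kg dry weight.
#' @examples
#' pec_soil_initial(25, 4, get_husbandry_defaults("piglet"))
#' @export
pec_soil_initial <- function(dose, duration, husbandry,
                             soil = soil_scenario(),
                             fraction_treated = NULL) {
  if (inherits(husbandry, "husbandry_defaults")) {
    H <- husbandry$composite_factor_H
    if (is.null(fraction_treated)) fraction_treated <- husbandry$fraction_treated
  } else {
    H <- husbandry
    if (is.null(fraction_treated)) fraction_treated <- 1
  }
  stop_if_not_positive(dose = dose, .allow_zero = TRUE)
  stop_if_not_positive(duration = duration, H = H,
                       fraction_treated = fraction_treated)
  if (fraction_treated > 1) stop("fraction_treated must be <= 1", call. = FALSE)
  dose * duration * fraction_treated * H * soil$nitrogen_limit * 1000 /
    (soil$bulk_density * soil$hectare_area * soil$mixing_depth_phase1)
}

#' Soil concentration rediluted over the deep mixing layer
#'
#' The Phase I residue mass sits in the shallow layer; for the groundwater
#' pathway the same mass is considered homogenised over the deeper layer,
#' scaling the concentration by the depth ratio.
#'
#' @param pec_soil Phase I soil concentration, ug/kg.
#' @param soil a [soil_scenario()].
#' @return soil concentration in the deep layer, ug/kg.
#' @examples
#' pec_soil_at_depth(868.88)  # 217.22 under the default 5 cm -> 20 cm
#' @export
pec_soil_at_depth <- function(pec_soil, soil = soil_scenario()) {
  stop_if_not_positive(pec_soil = pec_soil, .allow_zero = TRUE)
  pec_soil * soil$mixing_depth_phase1 / soil$mixing_depth_deep
}

#' Soil-water partition factor
#'
#' Tier A equilibrium partitioning between bulk soil and pore water,
#' `f = 0.1176 + 0.01764 * Koc` (L/kg): the intercept is the water-filled
#' pore volume contribution and the slope the organic-carbon fraction of the
#' standard soil. A `partition_factor_override` on the substance replaces
#' the computed value verbatim.
#'
#' @param substance a [substance_properties()] object.
#' @return partition factor, L/kg.
#' @examples
#' partition_factor(substance_properties("x", koc = 421))  # 7.544
#' @export
partition_factor <- function(substance) {
  if (!is.null(substance$partition_factor_override)) {
    return(substance$partition_factor_override)
  }
  0.1176 + 0.01764 * substance$koc
}

# suspended-matter / sediment accumulation factor of the Tier A chain
sediment_accumulation_factor <- function(substance) {
  0.783 + 0.0217 * substance$koc
}

#' Tier A groundwater concentration
#'
#' Pore-water concentration of the deep (20 cm) soil layer: the deep-layer
#' soil concentration divided by the soil-water partition factor.
#'
#' @param pec_soil_deep deep-layer soil concentration, ug/kg.
#' @param f soil-water partition factor, L/kg (> 0).
#' @return groundwater concentration, ug/L.
#' @examples
#' pec_groundwater(217.22, 7.69)  # 28.25
#' @export
pec_groundwater <- function(pec_soil_deep, f) {
  stop_if_not_positive(pec_soil_deep = pec_soil_deep, .allow_zero = TRUE)
  stop_if_not_positive(f = f)
  pec_soil_deep / f
}

#' Tier A surface-water concentration
#'
#' Pore water of the shallow (5 cm) layer diluted into the receiving surface
#' water body by the scenario dilution factor (default 3).
#'
#' @param pec_soil Phase I (shallow-layer) soil concentration, ug/kg.
#' @param f soil-water partition factor, L/kg (> 0).
#' @param soil a [soil_scenario()].
#' @return surface-water concentration, ug/L.
#' @examples
#' pec_surfacewater(868.88, 7.69)  # 37.66
#' @export
pec_surfacewater <- function(pec_soil, f, soil = soil_scenario()) {
  stop_if_not_positive(pec_soil = pec_soil, .allow_zero = TRUE)
  stop_if_not_positive(f = f, dilution = soil$surface_water_dilution)
  (pec_soil / f) / soil$surface_water_dilution
}

#' Tier A sediment concentration
#'
#' Default mode partitions the surface-water concentration onto sediment
#' with the suspended-matter accumulation factor `0.783 + 0.0217 * Koc`.
#' `override` mode returns a stored value instead — provided for reproducing
#' published chains whose sediment figure is not derivable from the stated
#' formulas.
#'
#' @param pec_sw surface-water concentration, ug/L.
#' @param substance a [substance_properties()] object.
#' @param override optional stored sediment concentration, ug/kg.
#' @return sediment concentration, ug/kg.
#' @examples
#' pec_sediment(37.66, substance_properties("x", koc = 421))  # 373.56
#' @export
pec_sediment <- function(pec_sw, substance, override = NULL) {
  stop_if_not_positive(pec_sw = pec_sw, .allow_zero = TRUE)
  if (!is.null(override)) {
    stop_if_not_positive(override = override, .allow_zero = TRUE)
    return(override)
  }
  pec_sw * sediment_accumulation_factor(substance)
}

#' Predicted environmental concentration matrix
#'
#' Runs the full Tier A exposure chain for every regimen of the scenario:
#' Phase I soil, deep-layer soil, groundwater, surface water and sediment.
#' The worst-case species (largest Phase I soil PEC; ties broken by
#' declaration order) is flagged, and the headline Phase II values — the
#' ones a tiered assessment carries forward — are those of that species.
#'
#' When `sediment_override` is supplied it pins the worst-case sediment
#' value; other species scale by their surface-water PEC so the matrix stays
#' homogeneous of degree one in dose.
#'
#' @param scenario a [product_scenario()].
#' @param substance a [substance_properties()].
#' @param registry a [husbandry_registry()].
#' @param soil a [soil_scenario()].
#' @param sediment_override optional stored worst-case sediment PEC, ug/kg.
#' @return An object of class `pec_matrix`: a long data frame
#'   (species, compartment, value, unit) with attributes
#'   `worst_case_species`, `intermediates` (deep-layer soil and pore-water
#'   concentrations per species) and `partition_factor`.
#' @export
build_pec_matrix <- function(scenario, substance,
                             registry = husbandry_registry(),
                             soil = soil_scenario(),
                             sediment_override = NULL) {
  stopifnot(inherits(scenario, "product_scenario"),
            inherits(substance, "substance_properties"))
  reg <- scenario$regimens
  f <- partition_factor(substance)

  rows <- lapply(seq_len(nrow(reg)), function(i) {
    r <- reg[i, ]
    hd <- get_husbandry_defaults(r$species, registry)
    ft <- if ("fraction_treated" %in% names(reg) && !is.na(r$fraction_treated)) {
      r$fraction_treated
    } else hd$fraction_treated
    p_soil <- pec_soil_initial(r$dose, r$duration, hd, soil, ft)
    p_deep <- pec_soil_at_depth(p_soil, soil)
    p_gw <- pec_groundwater(p_deep, f)
    p_sw <- pec_surfacewater(p_soil, f, soil)
    p_sed <- pec_sediment(p_sw, substance)
    list(species = r$species, soil = p_soil, soil_deep = p_deep,
         porewater = p_sw * soil$surface_water_dilution,
         groundwater = p_gw, surfacewater = p_sw, sediment = p_sed)
  })

  soil_vals <- vapply(rows, `[[`, numeric(1), "soil")
  worst <- reg$species[which.max(soil_vals)]  # which.max: first max wins

  if (!is.null(sediment_override)) {
    sw_worst <- rows[[which.max(soil_vals)]]$surfacewater
    if (sw_worst > 0) {
      scale <- sediment_override / sw_worst
      rows <- lapply(rows, function(r) {
        r$sediment <- r$surfacewater * scale
        r
      })
    }
  }

  long <- do.call(rbind, lapply(rows, function(r) {
    data.frame(
      species = r$species,
      compartment = c("soil", "groundwater", "surfacewater", "sediment"),
      value = c(r$soil, r$groundwater, r$surfacewater, r$sediment),
      unit = c("ug/kg", "ug/L", "ug/L", "ug/kg"),
      stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  structure(long,
            worst_case_species = worst,
            intermediates = do.call(rbind, lapply(rows, function(r) {
              data.frame(species = r$species, pec_soil_deep = r$soil_deep,
                         pec_porewater = r$porewater, stringsAsFactors = FALSE)
            })),
            partition_factor = f,
            class = c("pec_matrix", "data.frame"))
}

#' @export
print.pec_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("PEC matrix (worst-case species: %s, partition factor %.4f L/kg)\n",
              attr(x, "worst_case_species"), attr(x, "partition_factor")))
  y <- as.data.frame(x)
  y$value <- round(y$value, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @rdname build_pec_matrix
#' @param x a `pec_matrix`.
#' @param species,compartment selectors for a single entry.
#' @export
pec_value <- function(x, species, compartment) {
  hit <- x$species == species & x$compartment == compartment
  if (sum(hit) != 1L) {
    stop(sprintf("no PEC entry for (%s, %s)", species, compartment),
         call. = FALSE)
  }
  x$value[hit]
}
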