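# shared worked-example bundle (paper-mode overrides active)
ex_bundle <- penicillin_example()

# random single-species scenario for property/oracle tests; assumes a seed
# has been set by the caller
random_scenario_inputs <- function() {
  list(
    dose = stats::runif(1, 0.1, 60),
    duration = sample(1:10, 1),
    H = stats::runif(1, 5, 60),
    fraction_treated = stats::runif(1, 0.2, 1),
    koc = stats::runif(1, 0, 2000),
    noec_water = stats::runif(1, 0.5, 400),
    af_water = sample(c(10L, 100L, 1000L), 1)
  )
}

scenario_from_inputs <- function(inp, species = "sp1") {
  product_scenario(
    name = "random", ai_content = 100,
    regimens = data.frame(species = species, dose = inp$dose,
                          duration = inp$duration,
                          fraction_treated = inp$fraction_treated,
                          stringsAsFactors = FALSE))
}

registry_from_inputs <- function(inp, species = "sp1") {
  husbandry_registry(overrides = husbandry_override(species, inp$H))
}

endpoints_from_inputs <- function(inp) {
  ecotox_endpoints(data.frame(
    compartment = "water", organism = "algae", endpoint_type = "NOEC",
    value = inp$noec_water, unit = "mg/L",
    assessment_factor = inp$af_water, stringsAsFactors = FALSE))
}

substance_from_inputs <- function(inp) {
  substance_properties("random substance", koc = inp$koc)
}

# hand-composed scalar chain: the independent oracle for run_assessment
hand_composed_risk <- function(inp, soil = soil_scenario()) {
  p_soil <- inp$dose * inp$duration * inp$fraction_treated * inp$H *
    soil$nitrogen_limit * 1000 /
    (soil$bulk_density * soil$hectare_area * soil$mixing_depth_phase1)
  f <- 0.1176 + 0.01764 * inp$koc
  p_deep <- p_soil * soil$mixing_depth_phase1 / soil$mixing_depth_deep
  p_gw <- p_deep / f
  p_sw <- p_soil / f / soil$surface_water_dilution
  p_sed <- p_sw * (0.783 + 0.0217 * inp$koc)
  pnec_w <- inp$noec_water / inp$af_water                 # mg/L
  pnec_soil <- f * pnec_w                                 # mg/kg (EP only)
  pnec_sed <- (0.783 + 0.0217 * inp$koc) * pnec_w         # mg/kg
  list(
    pec_soil = p_soil, triggered = p_soil > 100,
    R = c(soil = (p_soil / 1000) / pnec_soil,
          groundwater = (p_gw / 1000) / pnec_w,
          surfacewater = (p_sw / 1000) / pnec_w,
          sediment = (p_sed / 1000) / pnec_sed)
  )
}
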