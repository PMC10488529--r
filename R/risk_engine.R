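#' Phase I trigger
#'
#' Phase I ends the assessment when the worst-case soil concentration stays
#' at or below 100 ug/kg; above the trigger the assessment proceeds to
#' Phase II. The comparison is strict (`> 100`).
#'
#' @param pec_soil Phase I soil concentration, ug/kg.
#' @return `TRUE` when Phase II is required.
#' @examples
#' phase1_trigger(868.88)  # TRUE
#' phase1_trigger(100)     # FALSE: the trigger is strict
#' @export
phase1_trigger <- function(pec_soil) {
  stop_if_not_positive(pec_soil = pec_soil, .allow_zero = TRUE)
  pec_soil > 100
}

#' Risk quotient
#'
#' `R = PEC / PNEC` after harmonising the two concentrations to a common
#' unit. `R < 1` means the predicted exposure stays below the no-effect
#' level.
#'
#' @param pec predicted environmental concentration.
#' @param pnec predicted no-effect concentration (> 0 after conversion).
#' @param pec_unit,pnec_unit units of the two inputs; must share a
#'   dimension (both per-volume or both per-mass).
#' @return dimensionless risk quotient.
#' @examples
#' risk_quotient(0.868, 7.69, "mg/kg", "mg/kg")      # 0.113
#' risk_quotient(37.66, 1, "ug/L", "mg/L")           # 0.03766
#' @export
risk_quotient <- function(pec, pnec, pec_unit = "mg/kg", pnec_unit = pec_unit) {
  stop_if_not_positive(pec = pec, .allow_zero = TRUE)
  pec_h <- convert_unit(pec, pec_unit, pnec_unit)
  stop_if_not_positive(pnec = pnec)
  pec_h / pnec
}

#' Refinement fractions for the exposure estimate
#'
#' The total-residue Phase I estimate assumes the full dose reaches soil
#' unchanged. When a risk quotient exceeds 1 the estimate may be refined by
#' the fraction actually excreted unmetabolized, the fraction surviving
#' storage/degradation in manure, and the fraction surviving degradation in
#' soil. Each fraction lies in (0, 1]; the default identity fractions leave
#' the PEC untouched.
#'
#' @param fraction_excreted fraction of the dose excreted unmetabolized.
#' @param fraction_after_manure fraction remaining after degradation in
#'   manure/feces.
#' @param fraction_after_soil fraction remaining after degradation in soil.
#' @return An object of class `refinement_inputs`.
#' @export
refinement_inputs <- function(fraction_excreted = 1,
                              fraction_after_manure = 1,
                              fraction_after_soil = 1) {
  for (nm in c("fraction_excreted", "fraction_after_manure",
               "fraction_after_soil")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v > 1) {
      stop(sprintf("'%s' must lie in (0, 1]", nm), call. = FALSE)
    }
  }
  structure(list(fraction_excreted = fraction_excreted,
                 fraction_after_manure = fraction_after_manure,
                 fraction_after_soil = fraction_after_soil),
            class = "refinement_inputs")
}

#' Refine a predicted concentration
#'
#' Multiplies the total-residue PEC by the three refinement fractions;
#' identity when all fractions are 1.
#'
#' @param pec concentration to refine (any unit; the result keeps it).
#' @param refinement a [refinement_inputs()].
#' @return refined concentration.
#' @examples
#' refine_pec(868.88, refinement_inputs(0.6, 0.5, 0.5))  # 130.33
#' @export
refine_pec <- function(pec, refinement = refinement_inputs()) {
  stopifnot(inherits(refinement, "refinement_inputs"))
  stop_if_not_positive(pec = pec, .allow_zero = TRUE)
  pec * refinement$fraction_excreted * refinement$fraction_after_manure *
    refinement$fraction_after_soil
}

new_trace <- function() {
  data.frame(step = character(), species = character(),
             quantity = character(), value = numeric(), unit = character(),
             stringsAsFactors = FALSE)
}

add_trace <- function(trace, step, quantity, value, unit, species = "-") {
  rbind(trace, data.frame(step = step, species = species, quantity = quantity,
                          value = value, unit = unit,
                          stringsAsFactors = FALSE))
}

#' Run the tiered decision tree
#'
#' Executes the full assessment: Phase I soil exposure for every species;
#' if no species exceeds the 100 ug/kg trigger the assessment stops there.
#' Otherwise Phase II Tier A computes the compartment PECs, the PNEC set,
#' and the species x compartment risk-quotient matrix. If every quotient is
#' below 1 the risk is acceptable and the assessment ends; otherwise the
#' exposure refinement fractions are applied and the tree records whether
#' refined exposure resolves the risk (`refine_pec`) or effect refinement
#' would be required next (`refine_pnec`).
#'
#' Every intermediate is appended to an ordered decision trace with its
#' conventional symbol (PECsoil_initial, PECsoil_20cm, PECgroundwater,
#' PNECwater, R_soil, ...).
#'
#' @param scenario a [product_scenario()].
#' @param substance a [substance_properties()].
#' @param endpoints an [ecotox_endpoints()] table.
#' @param registry a [husbandry_registry()].
#' @param soil a [soil_scenario()].
#' @param refinement a [refinement_inputs()]; identity by default.
#' @param sediment_override optional stored worst-case sediment PEC, ug/kg
#'   (see [pec_sediment()]).
#' @return An object of class `era_assessment`: list with `pec` (the
#'   [build_pec_matrix()] result), `pnec` (from [derive_pnecs()]), `risk`
#'   (long data frame species x compartment with `R`), `headline`
#'   (worst-case species quotients), `phase1` (per-species trigger flags),
#'   `conclusion` (one of `phase1_stop`, `acceptable_R_lt_1`, `refine_pec`,
#'   `refine_pnec`) and `trace`.
#' @export
run_assessment <- function(scenario, substance, endpoints,
                           registry = husbandry_registry(),
                           soil = soil_scenario(),
                           refinement = refinement_inputs(),
                           sediment_override = NULL) {
  stopifnot(inherits(scenario, "product_scenario"),
            inherits(substance, "substance_properties"),
            inherits(endpoints, "ecotox_endpoints"))
  trace <- new_trace()

  # Phase I
  reg <- scenario$regimens
  p1 <- vapply(seq_len(nrow(reg)), function(i) {
    hd <- get_husbandry_defaults(reg$species[i], registry)
    ft <- if ("fraction_treated" %in% names(reg) && !is.na(reg$fraction_treated[i])) {
      reg$fraction_treated[i]
    } else hd$fraction_treated
    pec_soil_initial(reg$dose[i], reg$duration[i], hd, soil, ft)
  }, numeric(1))
  names(p1) <- reg$species
  for (i in seq_along(p1)) {
    trace <- add_trace(trace, "phase1", "PECsoil_initial", p1[i], "ug/kg",
                       names(p1)[i])
  }
  triggered <- vapply(p1, phase1_trigger, logical(1))
  for (i in seq_along(triggered)) {
    trace <- add_trace(trace, "phase1", "trigger_gt_100",
                       as.numeric(triggered[i]), "flag", names(p1)[i])
  }

  if (!any(triggered)) {
    res <- list(pec = NULL, pnec = NULL, risk = NULL, headline = NULL,
                phase1 = data.frame(species = names(p1), pec_soil = unname(p1),
                                    triggered = unname(triggered),
                                    stringsAsFactors = FALSE),
                conclusion = "phase1_stop", refined = NULL, trace = trace)
    class(res) <- "era_assessment"
    return(res)
  }

  # Phase II, Tier A
  pec <- build_pec_matrix(scenario, substance, registry, soil,
                          sediment_override = sediment_override)
  worst <- attr(pec, "worst_case_species")
  inter <- attr(pec, "intermediates")
  f <- attr(pec, "partition_factor")
  trace <- add_trace(trace, "phase2", "partition_factor_f", f, "L/kg")
  trace <- add_trace(trace, "phase2", "worst_case_flag", 1, "flag", worst)
  deep <- inter$pec_soil_deep[inter$species == worst]
  trace <- add_trace(trace, "phase2", "PECsoil_20cm", deep, "ug/kg", worst)
  for (comp in c("groundwater", "surfacewater", "sediment")) {
    trace <- add_trace(trace, "phase2", paste0("PEC", comp),
                       pec_value(pec, worst, comp),
                       if (comp == "sediment") "ug/kg" else "ug/L", worst)
  }

  pnec <- derive_pnecs(endpoints, substance)
  for (nm in names(pnec)) {
    p <- pnec[[nm]]
    if (!is.null(p$af_value)) {
      trace <- add_trace(trace, "pnec", paste0("PNEC", nm, "_AF"),
                         p$af_value, p$unit)
    }
    if (!is.null(p$ep_value)) {
      trace <- add_trace(trace, "pnec", paste0("PNEC", nm, "_EP"),
                         p$ep_value, p$unit)
    }
    trace <- add_trace(trace, "pnec", paste0("PNEC", nm), p$selected, p$unit)
  }

  risk <- compute_risk_matrix(pec, pnec)
  for (i in seq_len(nrow(risk))) {
    trace <- add_trace(trace, "risk", paste0("R_", risk$compartment[i]),
                       risk$R[i], "-", risk$species[i])
  }
  headline <- risk[risk$species == worst, , drop = FALSE]

  if (all(risk$R < 1)) {
    conclusion <- "acceptable_R_lt_1"
    refined <- NULL
  } else {
    refined <- risk
    refined$R <- vapply(seq_len(nrow(risk)), function(i) {
      refine_pec(risk$R[i], refinement)  # R is linear in PEC
    }, numeric(1))
    for (i in seq_len(nrow(refined))) {
      trace <- add_trace(trace, "refine", paste0("R_refined_", refined$compartment[i]),
                         refined$R[i], "-", refined$species[i])
    }
    conclusion <- if (all(refined$R < 1)) "refine_pec" else "refine_pnec"
  }
  trace <- add_trace(trace, "conclusion", "conclusion",
                     match(conclusion, c("phase1_stop", "acceptable_R_lt_1",
                                         "refine_pec", "refine_pnec")), "enum")

  res <- list(pec = pec, pnec = pnec, risk = risk, headline = headline,
              phase1 = data.frame(species = names(p1), pec_soil = unname(p1),
                                  triggered = unname(triggered),
                                  stringsAsFactors = FALSE),
              conclusion = conclusion, refined = refined, trace = trace)
  class(res) <- "era_assessment"
  res
}

compute_risk_matrix <- function(pec, pnec) {
  pnec_for <- function(comp) {
    switch(comp,
           soil = pnec$soil, sediment = pnec$sediment,
           groundwater = pnec$water, surfacewater = pnec$water)
  }
  R <- vapply(seq_len(nrow(pec)), function(i) {
    p <- pnec_for(pec$compartment[i])
    risk_quotient(pec$value[i], p$selected, pec$unit[i], p$unit)
  }, numeric(1))
  out <- data.frame(species = pec$species, compartment = pec$compartment,
                    pec = pec$value, pec_unit = pec$unit,
                    pnec = vapply(pec$compartment,
                                  function(c) pnec_for(c)$selected, numeric(1)),
                    pnec_unit = vapply(pec$compartment,
                                       function(c) pnec_for(c)$unit, character(1)),
                    R = R, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.era_assessment <- function(x, ...) {
  cat("Tiered environmental risk assessment\n")
  cat("Phase I soil concentrations (trigger: > 100 ug/kg):\n")
  p1 <- x$phase1
  p1$pec_soil <- round(p1$pec_soil, 2)
  print(p1, row.names = FALSE)
  if (x$conclusion == "phase1_stop") {
    cat("Conclusion: phase1_stop (no species exceeds the trigger)\n")
    return(invisible(x))
  }
  cat(sprintf("\nWorst-case species: %s\n", attr(x$pec, "worst_case_species")))
  cat("\nRisk quotients (worst-case species):\n")
  h <- x$headline
  h$R <- round(h$R, 3)
  h$pec <- round(h$pec, 2)
  print(h[, c("compartment", "pec", "pec_unit", "pnec", "pnec_unit", "R")],
        row.names = FALSE)
  cat(sprintf("\nConclusion: %s\n", x$conclusion))
  invisible(x)
}
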