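test_that("the Phase I trigger is strict at 100 ug/kg", {
  expect_true(phase1_trigger(868.88))
  expect_false(phase1_trigger(100))
  expect_false(phase1_trigger(99.9))
  expect_true(phase1_trigger(100.0001))
})

test_that("risk quotients reproduce the worked-example table after unit harmonisation", {
  expect_equal(round(risk_quotient(0.868, 7.69, "mg/kg"), 3), 0.113)
  expect_equal(round(risk_quotient(1.721, 9.93, "mg/kg"), 3), 0.173)
  expect_equal(risk_quotient(37.66, 1, "ug/L", "mg/L"), 0.03766)
  expect_error(risk_quotient(1, 0, "mg/kg"), "positive")
  expect_error(risk_quotient(1, 1, "mg/kg", "mg/L"), "incompatible")
})

test_that("risk quotients are unit invariant to 1e-12 relative", {
  set.seed(5)
  for (rep in 1:20) {
    pec <- stats::runif(1, 0.001, 5000)
    pnec <- stats::runif(1, 0.001, 50)
    r_mg <- risk_quotient(pec / 1000, pnec, "mg/kg")
    r_ug <- risk_quotient(pec, pnec * 1000, "ug/kg")
    r_mixed <- risk_quotient(pec, pnec, "ug/kg", "mg/kg")
    expect_equal(r_ug, r_mg, tolerance = 1e-12)
    expect_equal(r_mixed, r_mg, tolerance = 1e-12)
  }
})

test_that("exposure refinement multiplies by the three fractions", {
  expect_equal(refine_pec(868.88, refinement_inputs(1, 1, 1)), 868.88)
  expect_equal(refine_pec(868.88, refinement_inputs(0.5, 1, 1)), 434.44)
  expect_equal(refine_pec(868.88, refinement_inputs(0.6, 0.5, 0.5)), 130.332)
  expect_error(refinement_inputs(0), "\\(0, 1\\]")
  expect_error(refinement_inputs(fraction_after_soil = 1.1), "\\(0, 1\\]")
})

test_that("the worked example concludes acceptable with the published quotients", {
  res <- run_assessment(ex_bundle$scenario, ex_bundle$substance,
                        ex_bundle$endpoints,
                        sediment_override = ex_bundle$sediment_override)
  expect_equal(res$conclusion, "acceptable_R_lt_1")
  expect_true(all(res$phase1$triggered))
  h <- res$headline
  r_of <- function(comp) h$R[h$compartment == comp]
  expect_equal(round(r_of("soil"), 3), 0.113)
  expect_equal(round(r_of("groundwater"), 3), 0.028)
  expect_equal(r_of("surfacewater"), 0.0376627, tolerance = 1e-4)
  expect_equal(r_of("sediment"), 1.721 / 9.9187, tolerance = 1e-6)
  expect_true(all(res$risk$R < 1))
})

test_that("a hundredfold dose reduction stops the assessment in Phase I", {
  reg <- ex_bundle$scenario$regimens
  reg$dose <- reg$dose * 0.01
  res <- run_assessment(product_scenario("low", 250, reg),
                        ex_bundle$substance, ex_bundle$endpoints)
  expect_equal(res$conclusion, "phase1_stop")
  expect_false(any(res$phase1$triggered))
  expect_null(res$risk)
  expect_equal(max(res$phase1$pec_soil), 8.6888, tolerance = 1e-4)
})

test_that("a low water PNEC routes to refinement, resolvable by exposure fractions", {
  strict <- ecotox_endpoints(data.frame(
    compartment = "water", organism = "algae", endpoint_type = "NOEC",
    value = 0.1, unit = "mg/L", assessment_factor = 10))  # PNECwater 0.01
  res <- run_assessment(ex_bundle$scenario, ex_bundle$substance, strict,
                        sediment_override = ex_bundle$sediment_override)
  expect_equal(res$conclusion, "refine_pnec")  # identity fractions leave R >= 1
  sw <- res$headline$R[res$headline$compartment == "surfacewater"]
  expect_equal(sw, 3.76627, tolerance = 1e-4)
  # strong exposure refinement brings every quotient below 1
  res2 <- run_assessment(ex_bundle$scenario, ex_bundle$substance, strict,
                         refinement = refinement_inputs(0.2, 0.5, 0.5),
                         sediment_override = ex_bundle$sediment_override)
  expect_equal(res2$conclusion, "refine_pec")
  expect_true(all(res2$refined$R < 1))
})

test_that("run_assessment equals the hand-composed scalar chain on random scenarios", {
  set.seed(1234)
  for (rep in 1:100) {
    inp <- random_scenario_inputs()
    oracle <- hand_composed_risk(inp)
    res <- run_assessment(scenario_from_inputs(inp),
                          substance_from_inputs(inp),
                          endpoints_from_inputs(inp),
                          registry = registry_from_inputs(inp))
    expect_equal(res$phase1$pec_soil, oracle$pec_soil, tolerance = 1e-12)
    if (!oracle$triggered) {
      expect_equal(res$conclusion, "phase1_stop")
    } else {
      got <- stats::setNames(res$risk$R, res$risk$compartment)
      expect_equal(got[names(oracle$R)], oracle$R, tolerance = 1e-10)
      expect_equal(res$conclusion,
                   if (all(oracle$R < 1)) "acceptable_R_lt_1" else "refine_pnec")
    }
  }
})

test_that("raising a PNEC or cutting dose never worsens the conclusion", {
  severity <- function(res) match(res$conclusion,
    c("phase1_stop", "acceptable_R_lt_1", "refine_pec", "refine_pnec"))
  set.seed(77)
  for (rep in 1:15) {
    inp <- random_scenario_inputs()
    base <- run_assessment(scenario_from_inputs(inp), substance_from_inputs(inp),
                           endpoints_from_inputs(inp),
                           registry = registry_from_inputs(inp))
    # more permissive endpoint (larger NOEC -> larger every PNEC)
    inp_hi <- inp; inp_hi$noec_water <- inp$noec_water * 10
    hi <- run_assessment(scenario_from_inputs(inp_hi), substance_from_inputs(inp_hi),
                         endpoints_from_inputs(inp_hi),
                         registry = registry_from_inputs(inp_hi))
    expect_lte(severity(hi), severity(base))
    # lower dose never raises severity
    inp_lo <- inp; inp_lo$dose <- inp$dose * 0.1
    lo <- run_assessment(scenario_from_inputs(inp_lo), substance_from_inputs(inp_lo),
                         endpoints_from_inputs(inp_lo),
                         registry = registry_from_inputs(inp_lo))
    expect_lte(severity(lo), severity(base))
  }
})

test_that("every headline figure appears in the decision trace", {
  res <- run_assessment(ex_bundle$scenario, ex_bundle$substance,
                        ex_bundle$endpoints,
                        sediment_override = ex_bundle$sediment_override)
  tr <- res$trace
  expect_gt(nrow(tr), 0)
  in_trace <- function(q, v) {
    any(tr$quantity == q & abs(tr$value - v) < 1e-9 * max(1, abs(v)))
  }
  for (i in seq_len(nrow(res$phase1))) {
    expect_true(in_trace("PECsoil_initial", res$phase1$pec_soil[i]))
  }
  worst <- attr(res$pec, "worst_case_species")
  for (comp in c("groundwater", "surfacewater", "sediment")) {
    expect_true(in_trace(paste0("PEC", comp), pec_value(res$pec, worst, comp)))
  }
  for (nm in names(res$pnec)) {
    expect_true(in_trace(paste0("PNEC", nm), res$pnec[[nm]]$selected))
  }
  for (i in seq_len(nrow(res$risk))) {
    expect_true(any(tr$quantity == paste0("R_", res$risk$compartment[i]) &
                      tr$species == res$risk$species[i] &
                      abs(tr$value - res$risk$R[i]) < 1e-12))
  }
})

test_that("a missing endpoint compartment fails with the compartment named", {
  no_water <- ecotox_endpoints(data.frame(
    compartment = "soil", organism = "earthworm", endpoint_type = "NOEC",
    value = 2000, unit = "mg/kg", assessment_factor = 100))
  expect_error(run_assessment(ex_bundle$scenario, ex_bundle$substance, no_water),
               "water")
})
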