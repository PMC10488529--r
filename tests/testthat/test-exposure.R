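test_that("Phase I soil PEC reproduces the worked-example values", {
  expect_equal(pec_soil_initial(25, 4, get_husbandry_defaults("piglet")),
               868.88, tolerance = 1e-5)
  expect_equal(pec_soil_initial(10, 4, get_husbandry_defaults("chicken")),
               354.78, tolerance = 1e-5)
  expect_equal(pec_soil_initial(0, 4, get_husbandry_defaults("piglet")), 0)
  expect_error(pec_soil_initial(-1, 4, 38), "non-negative")
  expect_error(pec_soil_initial(25, 4, 38, fraction_treated = 1.5), "<= 1")
})

test_that("deep-layer redistribution scales by the depth ratio", {
  expect_equal(pec_soil_at_depth(868.88), 868.88 * 5 / 20)
  expect_equal(pec_soil_at_depth(0), 0)
  # quarter rule under the default 5 -> 20 cm depths
  x <- stats::runif(5, 0, 1000)
  expect_equal(vapply(x, pec_soil_at_depth, numeric(1)), x / 4)
})

test_that("partition factor follows 0.1176 + 0.01764 * Koc with verbatim override", {
  expect_equal(partition_factor(substance_properties("x", koc = 0)), 0.1176)
  expect_equal(partition_factor(substance_properties("x", koc = 421)), 7.54404)
  expect_equal(partition_factor(
    substance_properties("x", koc = 421, partition_factor_override = 7.69)),
    7.69)
  # strictly increasing in koc
  ks <- seq(0, 2000, length.out = 20)
  fs <- vapply(ks, function(k) partition_factor(substance_properties("x", koc = k)),
               numeric(1))
  expect_true(all(diff(fs) > 0))
})

test_that("water and sediment PECs reproduce the worked-example chain", {
  # groundwater from the 20 cm layer; 217.22/7.69 = 28.247 (printed 28.24)
  expect_equal(pec_groundwater(217.22, 7.69), 28.2471, tolerance = 1e-4)
  expect_equal(pec_groundwater(217.22, 7.54404), 28.7936, tolerance = 1e-4)
  expect_equal(pec_groundwater(0, 7.69), 0)
  expect_error(pec_groundwater(217.22, 0), "positive")
  # surface water from the 5 cm layer with 3-fold dilution
  expect_equal(pec_surfacewater(868.88, 7.69), 37.66, tolerance = 1e-4)
  expect_equal(pec_surfacewater(868.88, 7.54404), 38.3915, tolerance = 1e-4)
  expect_equal(pec_surfacewater(0, 7.69), 0)
  # sediment: suspended-matter factor 0.783 + 0.0217*421 = 9.9187
  subst <- substance_properties("x", koc = 421)
  expect_equal(pec_sediment(37.66, subst), 37.66 * 9.9187)
  expect_equal(pec_sediment(0, subst), 0)
  expect_equal(pec_sediment(37.66, subst, override = 1721), 1721)
})

test_that("surface water equals groundwater * depth-ratio / dilution", {
  # under defaults: PECsw = PECgw * 4 / 3 (checkable: 28.24 * 4/3 = 37.65)
  soil <- soil_scenario()
  f <- 7.69
  p_soil <- 868.88
  gw <- pec_groundwater(pec_soil_at_depth(p_soil, soil), f)
  sw <- pec_surfacewater(p_soil, f, soil)
  expect_equal(sw, gw * 4 / 3, tolerance = 1e-12)
})

test_that("PEC matrix flags the worst case and breaks ties by declaration order", {
  m <- build_pec_matrix(ex_bundle$scenario, ex_bundle$substance,
                        sediment_override = ex_bundle$sediment_override)
  expect_equal(attr(m, "worst_case_species"), "piglet")
  expect_equal(pec_value(m, "piglet", "soil"), 868.88, tolerance = 1e-5)
  expect_equal(pec_value(m, "piglet", "sediment"), 1721)
  expect_true(all(m$value >= 0))
  # single species is its own worst case
  sc1 <- product_scenario("one", 250,
                          data.frame(species = "turkey", dose = 10, duration = 4))
  expect_equal(attr(build_pec_matrix(sc1, ex_bundle$substance), "worst_case_species"),
               "turkey")
  # equal soil PECs: first by declaration order
  reg <- husbandry_registry(overrides = rbind(
    husbandry_override("a", 10), husbandry_override("b", 10)))
  sc2 <- product_scenario("tie", 100,
                          data.frame(species = c("b", "a"), dose = 5, duration = 2))
  expect_equal(attr(build_pec_matrix(sc2, ex_bundle$substance, registry = reg),
                    "worst_case_species"), "b")
})

test_that("all PECs are homogeneous of degree one in dose", {
  base <- build_pec_matrix(ex_bundle$scenario, ex_bundle$substance,
                           sediment_override = ex_bundle$sediment_override)
  for (c_scale in c(0.01, 3.7)) {
    reg <- ex_bundle$scenario$regimens
    reg$dose <- reg$dose * c_scale
    scaled <- build_pec_matrix(
      product_scenario("scaled", 250, reg), ex_bundle$substance,
      sediment_override = ex_bundle$sediment_override * c_scale)
    expect_equal(scaled$value, base$value * c_scale, tolerance = 1e-12)
  }
})

test_that("water PECs strictly decrease as koc increases (no override)", {
  sw <- vapply(c(10, 100, 421, 1000), function(k) {
    m <- build_pec_matrix(ex_bundle$scenario,
                          substance_properties("x", koc = k))
    pec_value(m, "piglet", "surfacewater")
  }, numeric(1))
  expect_true(all(diff(sw) < 0))
})

test_that("matrix assembly equals hand-composition of the scalar ops", {
  set.seed(42)
  for (rep in 1:25) {
    inp <- random_scenario_inputs()
    m <- build_pec_matrix(scenario_from_inputs(inp),
                          substance_from_inputs(inp),
                          registry = registry_from_inputs(inp))
    oracle <- hand_composed_risk(inp)
    expect_equal(pec_value(m, "sp1", "soil"), oracle$pec_soil,
                 tolerance = 1e-12)
    f <- 0.1176 + 0.01764 * inp$koc
    expect_equal(pec_value(m, "sp1", "groundwater"),
                 oracle$pec_soil / 4 / f, tolerance = 1e-12)
    expect_equal(pec_value(m, "sp1", "surfacewater"),
                 oracle$pec_soil / f / 3, tolerance = 1e-12)
    expect_equal(pec_value(m, "sp1", "sediment"),
                 oracle$pec_soil / f / 3 * (0.783 + 0.0217 * inp$koc),
                 tolerance = 1e-12)
  }
})
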