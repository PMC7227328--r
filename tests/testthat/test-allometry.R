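test_that("estimate_biomass evaluates each functional form exactly", {
  pp <- allometric_model("pp", "power_product", c(a = 0.0673, b = 0.976),
                         dbh_range = c(5, 120))
  # direct evaluation oracle: a * (rho * D^2 * H)^b
  expect_equal(estimate_biomass(pp, 20, 10, 0.6),
               0.0673 * (0.6 * 400 * 10)^0.976, tolerance = 1e-12)
  pd <- allometric_model("pd", "power_dbh", c(a = 1, b = 1),
                         dbh_range = c(5, 100))
  expect_equal(estimate_biomass(pd, 7), 7)
  lin <- allometric_model("lin", "linear_combination",
                          c(a = -10, b = 2, c = 0), dbh_range = c(5, 50))
  expect_equal(estimate_biomass(lin, 5), 0)  # zero at the boundary
})

test_that("power-form biomass is strictly increasing in DBH", {
  pp <- allometric_model("pp", "power_product", c(a = 0.05, b = 0.9),
                         dbh_range = c(5, 80))
  d <- seq(5, 80, by = 0.5)
  b <- estimate_biomass(pp, d, height = 12, wood_density = 0.65)
  expect_true(all(diff(b) > 0))
  pd <- allometric_model("pd", "power_dbh", c(a = 0.2, b = 2.2),
                         dbh_range = c(5, 80))
  expect_true(all(diff(estimate_biomass(pd, d)) > 0))
})

test_that("doubling wood density doubles power_product biomass when b = 1", {
  m <- allometric_model("m", "power_product", c(a = 0.1, b = 1),
                        dbh_range = c(5, 100))
  expect_equal(estimate_biomass(m, 20, 10, 1.0),
               2 * estimate_biomass(m, 20, 10, 0.5))
})

test_that("invalid measurements and missing covariates are errors", {
  pp <- allometric_model("pp", "power_product", c(a = 0.0673, b = 0.976))
  expect_error(estimate_biomass(pp, -3, 10, 0.6), "positive")
  expect_error(estimate_biomass(pp, 20), "height")
  expect_error(estimate_biomass(pp, 20, -1, 0.6), "height")
  expect_error(estimate_biomass(pp, 20, 10, 2.0), "wood_density")
  expect_warning(estimate_biomass(pp, 150, 10, 0.6), "extrapolating")
})

test_that("model construction validates form and coefficients", {
  expect_error(allometric_model("x", "power_dbh", c(a = 1)), "needs")
  expect_error(allometric_model("x", "power_dbh", c(a = 1, b = Inf)),
               "finite")
  expect_error(allometric_model("x", "nope", c(a = 1, b = 1)))
})

test_that("routing order is species > LULC > default", {
  palm <- allometric_model("palm", "linear_combination",
                           c(a = 0, b = 2, c = 0.8),
                           species = c("Phoenix reclinata",
                                       "Borassus flabellifer"))
  shrub <- allometric_model("shrub", "power_dbh", c(a = 0.3, b = 2),
                            lulc = "Shrub Savannah")
  wood <- allometric_model("wood", "power_dbh", c(a = 0.2, b = 2.1),
                           lulc = "Savannah Woodland")
  dflt <- allometric_model("default", "power_dbh", c(a = 0.25, b = 2))
  reg <- model_registry(palm, shrub, wood, dflt)
  # palms beat any LULC match
  expect_equal(select_model(reg, "Phoenix reclinata",
                            "Shrub Savannah")$model_id, "palm")
  # LULC-specific beats the default
  expect_equal(select_model(reg, "Vitelaria paradoxa",
                            "Shrub Savannah")$model_id, "shrub")
  expect_equal(select_model(reg, "Vitelaria paradoxa",
                            "Savannah Woodland")$model_id, "wood")
  # otherwise the default resolves
  expect_equal(select_model(reg, "Vitelaria paradoxa",
                            "Cropland and Fallow")$model_id, "default")
})

test_that("single-model registries resolve everything to that model", {
  reg <- toy_registry()
  expect_equal(select_model(reg, "Vitelaria paradoxa",
                            "Cropland and Fallow")$model_id, "toy")
})

test_that("every (species, lulc) pair in the default design resolves", {
  reg <- default_registry()
  spec <- default_stand_spec()
  for (cl in spec$classes$lulc) {
    for (sp in names(spec$species_mix[[cl]])) {
      m <- select_model(reg, sp, cl)
      expect_s3_class(m, "allometric_model")
      expect_true(m$model_id %in% names(reg$models))
    }
  }
})

test_that("predict_biomass joins LULC from plots and applies routing", {
  plots <- toy_plots(2)
  trees <- tibble::tibble(
    plot_id = c("P01", "P02"), species = c("A sp", "B sp"),
    dbh_cm = c(10, 20), height_m = c(8, 10),
    wood_density_g_cm3 = 0.6)
  out <- predict_biomass(trees, toy_registry(), plots = plots)
  expect_setequal(out$biomass_kg, c(10, 20))  # B = D under identity model
  expect_error(predict_biomass(dplyr::mutate(trees, plot_id = "Q99"),
                               toy_registry(), plots = plots), "missing")
})
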