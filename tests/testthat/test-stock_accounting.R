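stocked_census <- function(biomass, species = "Alpha one",
                           plot_id = "P01") {
  tibble::tibble(plot_id = plot_id, species = species, dbh_cm = 10,
                 biomass_kg = biomass)
}

test_that("tree stocks apply the resolved fraction to biomass", {
  traits <- traits_table(packaged_traits())
  # unknown species: overall-mean fallback (47.01% C on 100 kg)
  s <- tree_stocks(stocked_census(100, "Mystery sp"), traits)
  expect_equal(s$carbon_kg, 47.01, tolerance = 1e-4)
  expect_equal(s$fraction_provenance, "fallback")
  # published nitrogen fraction of Entada Africana: 0.357% of 100 kg
  sn <- tree_stocks(stocked_census(100, "Entada Africana"), traits)
  expect_equal(sn$nitrogen_kg, 0.357)
  expect_equal(sn$fraction_provenance, "species-specific")
  # zero biomass, zero stocks
  z <- tree_stocks(stocked_census(0), traits)
  expect_equal(z$carbon_kg, 0)
  expect_equal(z$nitrogen_kg, 0)
  expect_error(tree_stocks(stocked_census(-1), traits), "non-negative")
})

test_that("plot stocks sum, convert units and keep empty plots", {
  traits <- toy_traits()
  plots <- toy_plots(2)
  stems <- tree_stocks(
    stocked_census(c(40, 60) / 0.46, "Alpha one"), traits)
  ps <- plot_stocks(stems, plots)
  p1 <- ps[ps$plot_id == "P01", ]
  # 40 + 60 kg C on 0.09 ha
  expect_equal(p1$carbon_mg, 0.1, tolerance = 1e-12)
  expect_equal(p1$carbon_mg_ha, 0.1 / 0.09, tolerance = 1e-12)
  # the treeless plot is a zero observation, not dropped
  p2 <- ps[ps$plot_id == "P02", ]
  expect_equal(p2$n_stems, 0)
  expect_equal(p2$carbon_mg_ha, 0)
  # 1000 kg C on 1 ha is 1 Mg/ha
  big <- plot_stocks(
    tree_stocks(stocked_census(1000 / 0.46, "Alpha one"), traits),
    tibble::tibble(plot_id = "P01", lulc = "X", width_m = 100,
                   length_m = 100))
  expect_equal(big$carbon_mg_ha, 1, tolerance = 1e-12)
})

test_that("class density is the mean of plot densities with SE = SD/sqrt(n)", {
  plots <- toy_plots(3)
  # craft plot densities of exactly {1, 2, 3} Mg C / ha
  traits <- toy_traits()
  cf <- 0.46
  stems <- tree_stocks(stocked_census(
    c(1, 2, 3) * 0.09 * 1000 / cf, "Alpha one",
    plot_id = plots$plot_id), traits)
  est <- lulc_stock_estimates(plot_stocks(stems, plots), element = "C")
  expect_equal(est$mean_density, 2, tolerance = 1e-12)
  expect_equal(est$se_density, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(est$min_density, 1, tolerance = 1e-12)
  expect_equal(est$max_density, 3, tolerance = 1e-12)
  # identical plots: zero spread
  same <- tree_stocks(stocked_census(
    rep(100, 3), "Alpha one", plot_id = plots$plot_id), traits)
  expect_equal(
    lulc_stock_estimates(plot_stocks(same, plots), "C")$se_density, 0)
})

test_that("totals scale density by class area", {
  est <- tibble::tibble(lulc = "X", element = "C", n_plots = 5L,
                        min_density = 0, max_density = 4,
                        mean_density = 2, se_density = 0.5)
  tot <- lulc_totals(est, tibble::tibble(lulc = "X", area_ha = 100))
  expect_equal(tot$total_mg, 200)
  expect_equal(tot$se_total_mg, 50)
  expect_error(lulc_totals(est, tibble::tibble(lulc = "X",
                                               area_ha = -1)), "positive")
  expect_error(lulc_totals(est, tibble::tibble(lulc = "Y",
                                               area_ha = 10)), "no area")
})

test_that("published grassland density times area matches its printed total", {
  # printed density is rounded to 2 dp, so the product can drift by up to
  # half a unit in the last printed digit times the area
  expect_lt(abs(1.67 * 96.48 - 161.55), 0.005 * 96.48)
})

test_that("landscape summary aggregates categories and grand totals", {
  est <- tibble::tibble(
    lulc = c("A", "B", "C"), element = "C", n_plots = 3L,
    min_density = 0, max_density = 1, mean_density = 1,
    se_density = 0.1, area_ha = c(10, 20, 30),
    total_mg = c(10, 20, 30), se_total_mg = c(1, 2, 3))
  ls <- landscape_summary(est, c(A = "Forest land", B = "Forest land",
                                 C = "Grassland"))
  expect_equal(ls$categories$total_mg[
    ls$categories$category == "Forest land"], 30)
  expect_equal(ls$categories$se_total_mg[
    ls$categories$category == "Forest land"], sqrt(1 + 4))
  expect_equal(ls$totals$total_mg, 60)
  # single class: subtotal equals the class total
  one <- landscape_summary(est[1, ], c(A = "Forest land"))
  expect_equal(one$categories$total_mg, 10)
  expect_error(landscape_summary(est, c(A = "Forest land")), "not mapped")
})

test_that("stocks are conserved across aggregation levels", {
  spec <- default_stand_spec()
  traits <- traits_table(packaged_traits())
  reg <- calibrate_registry(spec, default_registry(), traits)
  inv <- generate_inventory(spec, seed = 5)
  stems <- tree_stocks(predict_biomass(inv$trees, reg,
                                       plots = inv$plots), traits)
  ps <- plot_stocks(stems, inv$plots)
  expect_equal(sum(ps$carbon_mg), sum(stems$carbon_kg) / 1000,
               tolerance = 1e-9)
  # with class area set to the sampled area, class totals equal plot sums
  sampled <- ps |>
    dplyr::group_by(lulc) |>
    dplyr::summarise(area_ha = sum(area_ha), category = "All",
                     .groups = "drop")
  est <- lulc_stock_estimates(ps, element = "C", areas = sampled)
  expect_equal(sum(est$total_mg), sum(ps$carbon_mg), tolerance = 1e-9)
  ls <- landscape_summary(est)
  expect_equal(ls$totals$total_mg, sum(stems$carbon_kg) / 1000,
               tolerance = 1e-9)
})

test_that("stocks scale linearly with biomass", {
  traits <- toy_traits()
  plots <- toy_plots(2)
  base <- tree_stocks(stocked_census(
    c(120, 80), "Beta two", plot_id = plots$plot_id), traits)
  scaled <- tree_stocks(stocked_census(
    3 * c(120, 80), "Beta two", plot_id = plots$plot_id), traits)
  eb <- lulc_stock_estimates(plot_stocks(base, plots), "C")
  es <- lulc_stock_estimates(plot_stocks(scaled, plots), "C")
  expect_equal(es$mean_density, 3 * eb$mean_density, tolerance = 1e-12)
  expect_equal(es$se_density, 3 * eb$se_density, tolerance = 1e-12)
})

test_that("plot carbon-to-biomass ratio stays within applied fractions", {
  spec <- default_stand_spec()
  traits <- traits_table(packaged_traits())
  inv <- generate_inventory(spec, seed = 9)
  stems <- tree_stocks(predict_biomass(inv$trees, default_registry(),
                                       plots = inv$plots), traits)
  ps <- plot_stocks(stems, inv$plots)
  nonempty <- ps[ps$biomass_mg > 0, ]
  ratio <- nonempty$carbon_mg / nonempty$biomass_mg
  expect_true(all(ratio >= min(stems$carbon_fraction) - 1e-12))
  expect_true(all(ratio <= max(stems$carbon_fraction) + 1e-12))
})

test_that("nitrogen totals are strictly below carbon totals", {
  spec <- default_stand_spec()
  traits <- traits_table(packaged_traits())
  inv <- generate_inventory(spec, seed = 13)
  stems <- tree_stocks(predict_biomass(inv$trees, default_registry(),
                                       plots = inv$plots), traits)
  ps <- plot_stocks(stems, inv$plots)
  est <- lulc_stock_estimates(ps, element = "both",
                              areas = packaged_areas())
  ls <- landscape_summary(est)
  expect_lt(ls$totals$total_mg[ls$totals$element == "N"],
            ls$totals$total_mg[ls$totals$element == "C"])
})
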