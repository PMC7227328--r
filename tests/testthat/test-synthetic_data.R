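test_that("trait generation matches the campaign design and is seeded", {
  s1 <- generate_trait_samples(seed = 4)
  expect_equal(nrow(s1), 277)
  expect_equal(dplyr::n_distinct(s1$species), 18)
  expect_identical(s1, generate_trait_samples(seed = 4))
  expect_false(identical(s1, generate_trait_samples(seed = 5)))
})

test_that("generated traits respect the truncation envelopes", {
  spec <- trait_gen_spec()
  for (seed in c(2, 7, 31)) {
    s <- generate_trait_samples(spec, seed = seed)
    j <- dplyr::left_join(s, spec, by = "species")
    expect_true(all(j$carbon_pct >= j$c_min & j$carbon_pct <= j$c_max))
    expect_true(all(j$nitrogen_pct >= j$n_min &
                    j$nitrogen_pct <= j$n_max))
    expect_true(all(j$nitrogen_pct < j$carbon_pct))
  }
  bad <- spec
  bad$c_min[1] <- bad$c_max[1]
  expect_error(generate_trait_samples(bad, seed = 1), "infeasible")
})

test_that("generator sample means converge to the truncated-normal mean", {
  spec <- trait_gen_spec()
  picks <- c("Terminalia macroptera", "Anacardium occidentale",
             "Acacia seyal")
  trunc_mean <- function(m, sd, lo, hi) {
    a <- (lo - m) / sd; b <- (hi - m) / sd
    m + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  reps <- purrr::map_dfr(1:200, function(s)
    generate_trait_samples(spec, seed = s))
  for (sp in picks) {
    row <- spec[spec$species == sp, ]
    x <- reps$carbon_pct[reps$species == sp]
    mu <- trunc_mean(row$c_mean, row$c_sd, row$c_min, row$c_max)
    expect_lt(abs(mean(x) - mu), 3 * sd(x) / sqrt(length(x)))
  }
})

test_that("replicate species means track the published means", {
  spec <- trait_gen_spec()
  reps <- purrr::map_dfr(1:100, function(s)
    dplyr::mutate(summarize_species(generate_trait_samples(spec,
                                                           seed = s)),
                  rep = s))
  j <- dplyr::left_join(reps, spec, by = "species",
                        suffix = c("", ".spec"))
  covered <- abs(j$c_mean - j$c_mean.spec) <= 3 * j$c_sd / sqrt(j$n)
  expect_gt(mean(covered), 0.95)
})

test_that("the default stand design reproduces the plot layout", {
  spec <- default_stand_spec()
  expect_equal(sum(spec$classes$n_plots), 250)
  sampled <- sum(plot_area_ha(spec$classes$plot_width_m,
                              spec$classes$plot_length_m) *
                 spec$classes$n_plots)
  expect_equal(sampled, 27.26, tolerance = 1e-9)
  inv <- generate_inventory(spec, seed = 2)
  expect_equal(nrow(inv$plots), 250)
  expect_identical(generate_inventory(spec, seed = 2)$trees, inv$trees)
  expect_true(all(inv$trees$dbh_cm >= 5))
})

test_that("zero stem rates yield treeless plots and zero density", {
  spec <- default_stand_spec()
  spec$classes <- spec$classes[spec$classes$lulc == "Savannah grassland", ]
  spec$classes$stems_per_ha <- 0
  inv <- generate_inventory(spec, seed = 1)
  expect_equal(nrow(inv$plots), 34)
  expect_true(is.null(inv$trees) || nrow(inv$trees) == 0)
  traits <- traits_table(packaged_traits())
  ps <- plot_stocks(
    tree_stocks(tibble::tibble(plot_id = character(),
                               species = character(), dbh_cm = numeric(),
                               biomass_kg = numeric()), traits),
    inv$plots)
  est <- lulc_stock_estimates(ps, element = "C")
  expect_equal(est$mean_density, 0)
})

test_that("species missing from the mix tables are rejected", {
  spec <- default_stand_spec()
  spec$species_mix[["Savannah Woodland"]] <-
    c("Nonexistent sp" = 0.5, "Terminalia macroptera" = 0.5)
  expect_error(generate_inventory(spec, seed = 1), "wood density")
  bad <- default_stand_spec()
  bad$species_mix[["Savannah Woodland"]]["Acacia seyal"] <- 0.9
  expect_error(generate_inventory(bad, seed = 1), "sum to 1")
})

test_that("registry calibration makes expected density hit the target", {
  spec <- default_stand_spec()
  traits <- traits_table(packaged_traits())
  reg <- calibrate_registry(spec, default_registry(), traits)
  got <- expected_stock_density(spec, reg, traits, "C")
  j <- dplyr::left_join(spec$classes, got, by = "lulc")
  expect_equal(j$expected_density, j$target_c_density, tolerance = 1e-9)
})

test_that("truncated-lognormal moments match numerical integration", {
  mu <- log(12); s <- 0.45; L <- 5; U <- 45
  for (k in c(1, 2, 2.9)) {
    num <- integrate(function(x) x^k * dlnorm(x, mu, s) /
                       (plnorm(U, mu, s) - plnorm(L, mu, s)),
                     L, U, rel.tol = 1e-10)$value
    expect_equal(savstocks:::lnorm_trunc_moment(k, mu, s, L, U), num,
                 tolerance = 1e-8)
  }
})

test_that("pipeline recovers the generator's expected cropland density", {
  spec <- default_stand_spec()
  spec$classes <- spec$classes[spec$classes$lulc == "Cropland and Fallow", ]
  traits <- traits_table(packaged_traits())
  reg <- calibrate_registry(spec, default_registry(), traits)
  truth <- expected_stock_density(spec, reg, traits)$expected_density
  inv <- generate_inventory(spec, seed = 17)
  stems <- tree_stocks(predict_biomass(inv$trees, reg,
                                       plots = inv$plots), traits)
  est <- lulc_stock_estimates(plot_stocks(stems, inv$plots), "C")
  expect_lt(abs(est$mean_density - truth), 3 * est$se_density)
})

test_that("the area table matches the published design", {
  areas <- generate_area_table()
  expect_equal(areas$area_ha[areas$lulc == "Cropland and Fallow"],
               8031.15)
  expect_equal(areas$area_ha[areas$lulc == "Savannah Woodland"], 5447.79)
  # water, roads and bare land keep the percentages below 100
  expect_lt(sum(areas$percent_basin), 100)
  expect_equal(sum(areas$n_plots), 250)
})

test_that("class maps honour areas to within one cell per class", {
  areas <- generate_area_table()
  m <- generate_class_map(areas, resolution = 30, seed = 8)
  got <- class_map_areas(m)
  j <- dplyr::left_join(areas, got, by = "lulc")
  expect_true(all(abs(j$area_ha.x - j$area_ha.y) <= 0.09))
  expect_identical(generate_class_map(areas, resolution = 30, seed = 8)$values,
                   m$values)
  # a 2 km grid cannot represent the 16.74 ha plantation class
  expect_error(generate_class_map(areas, resolution = 2000, seed = 1),
               "too coarse")
})
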