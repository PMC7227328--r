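# Seeded synthetic data with the statistical structure of a savannah
# field campaign: per-species trait samples, a plot register + stem
# census per LULC class, the LULC area table, and a categorical class
# map. All generators are pure functions of (spec, seed).

#' Truncated-normal and truncated-lognormal samplers
#'
#' Inverse-CDF samplers used by the generators; exported because the
#' trait and DBH noise models are part of the package's documented
#' generating process.
#'
#' @param n Number of draws.
#' @param mean,sd Normal parameters (on the log scale for `rlnorm_trunc`).
#' @param lower,upper Truncation bounds (must satisfy `lower < upper`).
#' @return Numeric vector of length `n` inside `[lower, upper]`.
#' @export
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  if (lower >= upper) stop("infeasible truncation: lower >= upper",
                           call. = FALSE)
  if (sd <= 0) return(rep(pmin(pmax(mean, lower), upper), n))
  p <- runif(n, pnorm(lower, mean, sd), pnorm(upper, mean, sd))
  pmin(pmax(stats::qnorm(p, mean, sd), lower), upper)
}

#' @rdname rnorm_trunc
#' @export
rlnorm_trunc <- function(n, mean, sd, lower, upper) {
  exp(rnorm_trunc(n, mean, sd, log(lower), log(upper)))
}

# k-th moment of a lognormal(mu, s) truncated to [L, U]
lnorm_trunc_moment <- function(k, mu, s, L, U) {
  zl <- (log(L) - mu) / s
  zu <- (log(U) - mu) / s
  denom <- pnorm(zu) - pnorm(zl)
  if (denom <= 0) stop("infeasible truncation range", call. = FALSE)
  exp(k * mu + k^2 * s^2 / 2) * (pnorm(zu - k * s) - pnorm(zl - k * s)) /
    denom
}

#' Build a trait-generation spec from a published summary table
#'
#' Converts a per-species summary (n, min, max, mean, SE) into the
#' parameters of the trait noise model: a normal distribution with the
#' printed mean and SD = SE * sqrt(n), truncated to the printed
#' [min, max] — the simplest model consistent with all four printed
#' statistics.
#'
#' @param summary Traits summary data frame (see
#'   [read_traits_summary_csv()]); defaults to the packaged table.
#' @return A tibble with per-species generation parameters for C and N
#'   (percent of dry matter).
#' @export
trait_gen_spec <- function(summary = NULL) {
  if (is.null(summary)) {
    summary <- read_traits_summary_csv(
      savstocks_example("stem_wood_traits.csv"))
  }
  tibble::as_tibble(summary) |>
    dplyr::transmute(
      species = .data$species,
      n = .data$n_samples,
      c_mean = .data$c_mean, c_sd = .data$c_se * sqrt(.data$n_samples),
      c_min = .data$c_min, c_max = .data$c_max,
      n_mean = .data$n_mean, n_sd = .data$n_se * sqrt(.data$n_samples),
      n_min = .data$n_min, n_max = .data$n_max
    )
}

#' Generate per-sample wood C/N trait measurements
#'
#' Draws, for every species in the spec, exactly `n` stem-wood samples
#' with carbon and nitrogen percentages from truncated normal
#' distributions. Nitrogen is always below carbon by construction (the
#' nitrogen envelope lies two orders of magnitude below the carbon one);
#' the invariant is asserted anyway.
#'
#' @param spec A [trait_gen_spec()] tibble.
#' @param seed Integer seed; same seed, same output.
#' @return A tibble of wood samples (`species`, `carbon_pct`,
#'   `nitrogen_pct`).
#' @export
#' @examples
#' samples <- generate_trait_samples(seed = 1)
#' nrow(samples)  # 277 with the packaged spec
generate_trait_samples <- function(spec = trait_gen_spec(), seed = 1) {
  stopifnot(is.data.frame(spec), nrow(spec) >= 1)
  if (any(spec$c_min >= spec$c_max) || any(spec$n_min >= spec$n_max)) {
    stop("infeasible truncation: min >= max in trait spec", call. = FALSE)
  }
  out <- withr::with_seed(as.integer(seed), {
    purrr::pmap_dfr(spec, function(species, n, c_mean, c_sd, c_min, c_max,
                                   n_mean, n_sd, n_min, n_max, ...) {
      tibble::tibble(
        species = species,
        carbon_pct = rnorm_trunc(n, c_mean, c_sd, c_min, c_max),
        nitrogen_pct = rnorm_trunc(n, n_mean, n_sd, n_min, n_max)
      )
    })
  })
  stopifnot(all(out$nitrogen_pct < out$carbon_pct))
  out
}

#' Default per-species wood densities (g/cm3)
#'
#' Field-plausible basic wood densities for the species appearing in the
#' default stand spec; used when a census generator needs a density and
#' the user supplies none. Synthetic values, not measurements.
#'
#' @return Named numeric vector, g/cm3.
#' @export
default_wood_density <- function() {
  c("Terminalia macroptera" = 0.65, "Terminalia avicennioides" = 0.65,
    "Acacia seyal" = 0.70, "Acacia gourmaensis" = 0.68,
    "Combretum glutinosum" = 0.72, "Pterocarpus erinaceus" = 0.72,
    "Anogeisus leiocarpus" = 0.78, "Mitragyna inermis" = 0.63,
    "Lannea microcrapa" = 0.50, "Lannea acida" = 0.52,
    "Ficus sp" = 0.45, "Crosopteryx febrifuga" = 0.75,
    "Entada Africana" = 0.60, "Parkia biglobosa" = 0.58,
    "Vitelaria paradoxa" = 0.72, "Azadirachta indica" = 0.68,
    "Anacardium occidentale" = 0.55, "Eucalyptus grandis" = 0.60,
    "Tectona grandis" = 0.55, "Gmelina arborea" = 0.42,
    "Other species" = 0.60)
}

default_species_mix <- function() {
  list(
    "Riparian forest and woodland" = c(
      "Mitragyna inermis" = 0.20, "Pterocarpus erinaceus" = 0.15,
      "Anogeisus leiocarpus" = 0.15, "Ficus sp" = 0.10,
      "Terminalia macroptera" = 0.10, "Crosopteryx febrifuga" = 0.10,
      "Other species" = 0.20),
    "Savannah Woodland" = c(
      "Terminalia macroptera" = 0.15, "Pterocarpus erinaceus" = 0.10,
      "Anogeisus leiocarpus" = 0.10, "Combretum glutinosum" = 0.10,
      "Vitelaria paradoxa" = 0.10, "Parkia biglobosa" = 0.10,
      "Lannea microcrapa" = 0.10, "Acacia seyal" = 0.05,
      "Other species" = 0.20),
    "Shrub Savannah" = c(
      "Combretum glutinosum" = 0.25, "Acacia seyal" = 0.15,
      "Lannea microcrapa" = 0.15, "Lannea acida" = 0.10,
      "Terminalia macroptera" = 0.10, "Other species" = 0.25),
    "Savannah grassland" = c(
      "Vitelaria paradoxa" = 0.40, "Parkia biglobosa" = 0.30,
      "Lannea microcrapa" = 0.10, "Other species" = 0.20),
    "Cropland and Fallow" = c(
      "Vitelaria paradoxa" = 0.45, "Parkia biglobosa" = 0.30,
      "Lannea acida" = 0.05, "Other species" = 0.20),
    "Settlements" = c(
      "Azadirachta indica" = 0.50, "Anacardium occidentale" = 0.10,
      "Ficus sp" = 0.10, "Other species" = 0.30),
    "Cashew plantation" = c(
      "Anacardium occidentale" = 0.95, "Other species" = 0.05),
    "Plantation" = c(
      "Eucalyptus grandis" = 0.50, "Azadirachta indica" = 0.20,
      "Tectona grandis" = 0.15, "Gmelina arborea" = 0.15)
  )
}

#' Default stand-generation spec
#'
#' One row per LULC class with the sampling design (plot counts and
#' dimensions as established in the field campaign: 250 plots, 27.26 ha),
#' the stem rate (published figures where available: 1397 stems/ha in
#' riparian forest, 300 in cashew plantations; field-plausible rates
#' elsewhere), a truncated-lognormal DBH distribution, a power-law height
#' model H = h0 * D^h1 * exp(noise), and the target mean carbon density
#' each class is calibrated to (the published class densities; the
#' Plantation target is its published total stock divided by its area,
#' since the published table splits that class by planted species).
#'
#' @param areas LULC area table (defaults to the packaged one).
#' @param reference Reference density table (defaults to the packaged
#'   one) supplying the calibration targets.
#' @return An object of class `stand_spec`: list with `classes` (tibble),
#'   `species_mix`, `wood_density`, `wood_density_sigma` (lognormal SD of
#'   the per-stem density noise), and `nb_size` (negative-binomial
#'   dispersion of stems per plot).
#' @export
default_stand_spec <- function(areas = NULL, reference = NULL) {
  if (is.null(areas)) {
    areas <- read_area_csv(savstocks_example("lulc_areas.csv"))
  }
  if (is.null(reference)) {
    reference <- readr::read_csv(
      savstocks_example("carbon_density_reference.csv"),
      show_col_types = FALSE)
  }
  ref_c <- dplyr::filter(reference, .data$element == "C")
  target_for <- function(lulc, category, area_ha) {
    hit <- ref_c$mean_density[ref_c$lulc == lulc]
    if (length(hit)) return(hit[1])
    # class split into sub-classes in the reference: category total / area
    sub <- ref_c[ref_c$category == category, ]
    sum(sub$total_stock) / area_ha
  }
  cls <- tibble::as_tibble(areas) |>
    dplyr::mutate(
      stems_per_ha = c(
        "Riparian forest and woodland" = 1397, "Savannah Woodland" = 700,
        "Shrub Savannah" = 450, "Savannah grassland" = 30,
        "Cropland and Fallow" = 25, "Settlements" = 60,
        "Cashew plantation" = 300, "Plantation" = 700)[.data$lulc],
      dbh_meanlog = log(c(
        "Riparian forest and woodland" = 11, "Savannah Woodland" = 12,
        "Shrub Savannah" = 10, "Savannah grassland" = 15,
        "Cropland and Fallow" = 15, "Settlements" = 14,
        "Cashew plantation" = 18, "Plantation" = 15)[.data$lulc]),
      dbh_sdlog = c(
        "Riparian forest and woodland" = 0.50, "Savannah Woodland" = 0.45,
        "Shrub Savannah" = 0.40, "Savannah grassland" = 0.50,
        "Cropland and Fallow" = 0.50, "Settlements" = 0.50,
        "Cashew plantation" = 0.35, "Plantation" = 0.40)[.data$lulc],
      dbh_min = 5,
      dbh_max = c(
        "Riparian forest and woodland" = 60, "Savannah Woodland" = 45,
        "Shrub Savannah" = 35, "Savannah grassland" = 50,
        "Cropland and Fallow" = 60, "Settlements" = 50,
        "Cashew plantation" = 60, "Plantation" = 35)[.data$lulc],
      height_a = 1.3, height_b = 0.65, height_sigma = 0.15,
      target_c_density = purrr::pmap_dbl(
        list(.data$lulc, .data$category, .data$area_ha), target_for)
    ) |>
    dplyr::select("lulc", "category", "area_ha", "n_plots",
                  "plot_width_m", "plot_length_m", "stems_per_ha",
                  dplyr::starts_with("dbh_"),
                  dplyr::starts_with("height_"), "target_c_density")
  structure(
    list(classes = cls, species_mix = default_species_mix(),
         wood_density = default_wood_density(),
         wood_density_sigma = 0.05, nb_size = 5),
    class = "stand_spec"
  )
}

#' @export
print.stand_spec <- function(x, ...) {
  cat("<stand_spec> ", nrow(x$classes), " LULC classes, ",
      sum(x$classes$n_plots), " plots, ",
      sprintf("%.2f", sum(plot_area_ha(x$classes$plot_width_m,
                                       x$classes$plot_length_m) *
                          x$classes$n_plots)),
      " ha sampled\n", sep = "")
  print(x$classes)
  invisible(x)
}

validate_stand_spec <- function(spec, traits = NULL) {
  stopifnot(inherits(spec, "stand_spec"))
  mixes <- spec$species_mix[spec$classes$lulc]
  if (any(vapply(mixes, is.null, logical(1)))) {
    stop("species mix missing for some LULC class", call. = FALSE)
  }
  psum <- vapply(mixes, sum, numeric(1))
  if (any(abs(psum - 1) > 1e-8)) {
    stop("species-mix probabilities must sum to 1", call. = FALSE)
  }
  all_sp <- unique(unlist(lapply(mixes, names)))
  missing_wd <- setdiff(all_sp, names(spec$wood_density))
  if (length(missing_wd)) {
    stop("no wood density for species: ",
         paste(missing_wd, collapse = ", "), call. = FALSE)
  }
  invisible(spec)
}

#' Analytic expected carbon density of a stand spec
#'
#' Closed-form expectation of the per-hectare carbon stock implied by a
#' stand spec under a model registry and traits table. For each species
#' in a class's mix, the expected biomass of one stem is evaluated from
#' truncated-lognormal DBH moments and the lognormal height/wood-density
#' noise factors; fractions then convert biomass to carbon, and the stem
#' rate scales to Mg/ha. This is the ground truth that parameter-recovery
#' tests compare pipeline estimates against.
#'
#' @param spec A `stand_spec`.
#' @param registry A [model_registry()].
#' @param traits A [traits_table()].
#' @param element `"C"` or `"N"`.
#' @return Tibble with `lulc` and `expected_density` (Mg/ha).
#' @export
expected_stock_density <- function(spec, registry, traits,
                                   element = "C") {
  validate_stand_spec(spec)
  stopifnot(inherits(registry, "model_registry"),
            inherits(traits, "traits_table"))
  sig_wd <- spec$wood_density_sigma
  rows <- purrr::pmap_dfr(spec$classes, function(lulc, stems_per_ha,
      dbh_meanlog, dbh_sdlog, dbh_min, dbh_max, height_a, height_b,
      height_sigma, ...) {
    mix <- spec$species_mix[[lulc]]
    fr <- fraction_for_species(traits, names(mix), element)$fraction
    eb <- vapply(names(mix), function(sp) {
      m <- select_model(registry, sp, lulc)
      expected_biomass_kg(m, dbh_meanlog, dbh_sdlog, dbh_min, dbh_max,
                          height_a, height_b, height_sigma,
                          spec$wood_density[[sp]], sig_wd)
    }, numeric(1))
    tibble::tibble(
      lulc = lulc,
      expected_density = stems_per_ha * sum(mix * fr * eb) / 1000
    )
  })
  rows
}

# E[B] in kg for one stem under the generating distributions
expected_biomass_kg <- function(model, mu, s, L, U, h_a, h_b, h_sigma,
                                wd_mean, wd_sigma) {
  cf <- model$coefficients
  switch(model$form,
    power_product = {
      b <- cf[["b"]]
      k <- (2 + h_b) * b
      # wood-density noise is lognormal with mean 1; E[rho^b] picks up
      # the usual exp(b(b-1)sigma^2/2) correction
      e_rho <- wd_mean^b * exp(b * (b - 1) * wd_sigma^2 / 2)
      e_h <- h_a^b * exp(b^2 * h_sigma^2 / 2)
      cf[["a"]] * e_rho * e_h * lnorm_trunc_moment(k, mu, s, L, U)
    },
    power_dbh = cf[["a"]] * lnorm_trunc_moment(cf[["b"]], mu, s, L, U),
    linear_combination =
      cf[["a"]] + cf[["b"]] * lnorm_trunc_moment(1, mu, s, L, U) +
      cf[["c"]] * lnorm_trunc_moment(2, mu, s, L, U)
  )
}

scale_model <- function(model, factor) {
  cf <- model$coefficients
  if (model$form == "linear_combination") cf <- cf * factor
  else cf[["a"]] <- cf[["a"]] * factor
  model$coefficients <- cf
  model
}

#' Calibrate a registry so expected densities hit the spec targets
#'
#' Rescales, per LULC class, the allometric scale coefficient of the
#' model that class routes to, so that the analytic expected carbon
#' density ([expected_stock_density()]) equals the spec's
#' `target_c_density`. Biomass is linear in the scale coefficient, so the
#' calibration is exact and deterministic. Requires each class's species
#' to resolve to a single model; the calibrated registry contains one
#' class-restricted clone per class plus the original default.
#'
#' @inheritParams expected_stock_density
#' @return A calibrated [model_registry()].
#' @export
calibrate_registry <- function(spec, registry, traits) {
  validate_stand_spec(spec)
  expected <- expected_stock_density(spec, registry, traits, "C")
  models <- list()
  for (i in seq_len(nrow(spec$classes))) {
    lulc <- spec$classes$lulc[i]
    mix_sp <- names(spec$species_mix[[lulc]])
    resolved <- unique(vapply(mix_sp, function(sp)
      select_model(registry, sp, lulc)$model_id, character(1)))
    if (length(resolved) != 1L) {
      stop("class '", lulc, "' routes to several models (",
           paste(resolved, collapse = ", "),
           "); calibration needs a single model per class", call. = FALSE)
    }
    target <- spec$classes$target_c_density[i]
    cur <- expected$expected_density[expected$lulc == lulc]
    m <- scale_model(registry$models[[resolved]], target / cur)
    m$model_id <- paste0(resolved, "::", lulc)
    m$species <- character()
    m$lulc <- lulc
    models[[m$model_id]] <- m
  }
  models[["uncalibrated-default"]] <-
    registry$models[[registry$default]]
  models[["uncalibrated-default"]]$model_id <- "uncalibrated-default"
  model_registry(models, default = "uncalibrated-default")
}

#' Generate a plot register and stem census
#'
#' Draws, for every LULC class in the spec, its plots (counts and sizes
#' from the design) and the stems on each plot: stem counts are negative
#' binomial with mean `stems_per_ha * plot area` and dispersion
#' `nb_size` (between-plot variability in these landscapes is strongly
#' overdispersed), species from the class mix, DBH from the truncated
#' lognormal, height from the power-law model with lognormal noise, and
#' wood density from the species mean with lognormal noise of mean 1.
#'
#' @param spec A `stand_spec` (default [default_stand_spec()]).
#' @param seed Integer seed.
#' @return List with `plots` (plot register tibble) and `trees` (census
#'   tibble with `plot_id`, `lulc`, `species`, `dbh_cm`, `height_m`,
#'   `wood_density_g_cm3`).
#' @export
#' @examples
#' inv <- generate_inventory(seed = 42)
#' nrow(inv$plots)  # 250 with the default design
generate_inventory <- function(spec = default_stand_spec(), seed = 1) {
  validate_stand_spec(spec)
  withr::with_seed(as.integer(seed), {
    plots <- spec$classes |>
      dplyr::rowwise() |>
      dplyr::reframe(
        plot_id = sprintf("%s_%03d", gsub("[^A-Za-z]+", "", .data$lulc),
                          seq_len(.data$n_plots)),
        lulc = .data$lulc,
        width_m = .data$plot_width_m,
        length_m = .data$plot_length_m
      )
    trees <- purrr::pmap_dfr(spec$classes, function(lulc, n_plots,
        plot_width_m, plot_length_m, stems_per_ha, dbh_meanlog,
        dbh_sdlog, dbh_min, dbh_max, height_a, height_b, height_sigma,
        ...) {
      area <- plot_area_ha(plot_width_m, plot_length_m)
      counts <- rnbinom(n_plots, mu = stems_per_ha * area,
                        size = spec$nb_size)
      n_tot <- sum(counts)
      if (n_tot == 0L) return(NULL)
      ids <- sprintf("%s_%03d", gsub("[^A-Za-z]+", "", lulc),
                     seq_len(n_plots))
      mix <- spec$species_mix[[lulc]]
      sp <- sample(names(mix), n_tot, replace = TRUE, prob = mix)
      dbh <- rlnorm_trunc(n_tot, dbh_meanlog, dbh_sdlog, dbh_min, dbh_max)
      h <- height_a * dbh^height_b * exp(rnorm(n_tot, 0, height_sigma))
      wd <- spec$wood_density[sp] *
        exp(rnorm(n_tot, -spec$wood_density_sigma^2 / 2,
                  spec$wood_density_sigma))
      tibble::tibble(
        plot_id = rep(ids, counts), lulc = lulc, species = sp,
        dbh_cm = dbh, height_m = h,
        wood_density_g_cm3 = pmin(pmax(unname(wd), 0.1), 1.5)
      )
    })
    list(plots = tibble::as_tibble(plots), trees = trees)
  })
}

#' The LULC area table of the study design
#'
#' @return The packaged area table as a tibble: `lulc`, `category`,
#'   `area_ha`, `percent_basin`, `area_sampled_ha`, `n_plots`,
#'   `plot_width_m`, `plot_length_m`. Percentages do not sum to 100
#'   because water bodies, roads and bare land are excluded.
#' @export
generate_area_table <- function() {
  read_area_csv(savstocks_example("lulc_areas.csv"))
}
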