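# Small deterministic fixtures built in code.

toy_traits_summary <- function() {
  tibble::tibble(
    species = c("Alpha one", "Beta two", "Gamma three"),
    n_samples = c(5L, 4L, 3L),
    c_min = c(44, 45, 46), c_max = c(48, 49, 50),
    c_mean = c(46, 47, 48), c_se = c(0.5, 0.4, 0.6),
    n_min = c(0.1, 0.15, 0.2), n_max = c(0.3, 0.35, 0.4),
    n_mean = c(0.2, 0.25, 0.3), n_se = c(0.02, 0.02, 0.03)
  )
}

toy_traits <- function(...) traits_table(toy_traits_summary(), ...)

# identity-friendly diameter-only model: B = a * D^b
toy_registry <- function(a = 1, b = 1) {
  model_registry(allometric_model("toy", "power_dbh", c(a = a, b = b),
                                  dbh_range = c(5, 100)))
}

toy_plots <- function(n = 3, lulc = "Savannah Woodland",
                      width = 30, length = 30) {
  tibble::tibble(
    plot_id = sprintf("P%02d", seq_len(n)), lulc = lulc,
    width_m = width, length_m = length
  )
}

# census matching a hand-computed IVI table:
# A: 6 stems of 10 cm in 3 plots; B: 3 stems of 20 cm in 2 plots;
# C: 1 stem of 30 cm in 1 plot
toy_census <- function() {
  tibble::tibble(
    plot_id = c("P01", "P01", "P02", "P02", "P03", "P03",
                "P01", "P02", "P02", "P01"),
    species = c(rep("A", 6), rep("B", 3), "C"),
    dbh_cm = c(rep(10, 6), rep(20, 3), 30),
    height_m = 8,
    wood_density_g_cm3 = 0.6
  )
}

# the published trait summary and area tables shipped with the package
packaged_traits <- function() {
  read_traits_summary_csv(savstocks_example("stem_wood_traits.csv"))
}
packaged_areas <- function() {
  read_area_csv(savstocks_example("lulc_areas.csv"))
}
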