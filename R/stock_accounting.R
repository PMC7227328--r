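#' Carbon and nitrogen stock of each stem
#'
#' Applies the element fractions to per-stem biomass: the stock of element
#' E in a tree is `fraction_E * biomass`, with the species-specific mean
#' fraction when the species is in the traits table and the overall mean
#' otherwise (the provenance column records which path was taken).
#'
#' @param trees Census with a `biomass_kg` column (see [predict_biomass()])
#'   and a `species` column.
#' @param traits A [traits_table()].
#' @return `trees` with columns `carbon_fraction`, `nitrogen_fraction`
#'   (proportions of dry matter), `fraction_provenance`, `carbon_kg`,
#'   `nitrogen_kg` appended.
#' @export
tree_stocks <- function(trees, traits) {
  stopifnot(is.data.frame(trees), inherits(traits, "traits_table"))
  if (!"biomass_kg" %in% names(trees)) {
    stop("trees need a biomass_kg column; run predict_biomass() first",
         call. = FALSE)
  }
  if (nrow(trees) && any(trees$biomass_kg < 0)) {
    stop("biomass must be non-negative", call. = FALSE)
  }
  cfrac <- fraction_for_species(traits, trees$species, "C")
  nfrac <- fraction_for_species(traits, trees$species, "N")
  tibble::as_tibble(trees) |>
    dplyr::mutate(
      carbon_fraction = cfrac$fraction,
      nitrogen_fraction = nfrac$fraction,
      fraction_provenance = cfrac$provenance,
      carbon_kg = .data$carbon_fraction * .data$biomass_kg,
      nitrogen_kg = .data$nitrogen_fraction * .data$biomass_kg
    )
}

#' Per-plot stocks and densities
#'
#' Sums tree-level stocks within each plot, converts kg to Mg, and
#' divides by the plot area for densities. Plots with no stems are kept as
#' legitimate zero observations — near-empty grassland and cropland plots
#' carry real information about the class mean.
#'
#' @param tree_stocks Output of [tree_stocks()].
#' @param plots Plot register (`plot_id`, `lulc`, `width_m`, `length_m`).
#' @return A tibble with one row per plot: `plot_id`, `lulc`, `area_ha`,
#'   `n_stems`, `biomass_mg`, `carbon_mg`, `nitrogen_mg`,
#'   `carbon_mg_ha`, `nitrogen_mg_ha`.
#' @export
plot_stocks <- function(tree_stocks, plots) {
  validate_plots(plots)
  stopifnot(is.data.frame(tree_stocks))
  if (nrow(tree_stocks)) {
    validate_trees(tree_stocks, plots)
    req <- c("carbon_kg", "nitrogen_kg", "biomass_kg")
    if (!all(req %in% names(tree_stocks))) {
      stop("run tree_stocks() before plot_stocks()", call. = FALSE)
    }
  }
  sums <- tibble::as_tibble(tree_stocks) |>
    dplyr::group_by(.data$plot_id) |>
    dplyr::summarise(
      n_stems = dplyr::n(),
      biomass_mg = sum(.data$biomass_kg) / 1000,
      carbon_mg = sum(.data$carbon_kg) / 1000,
      nitrogen_mg = sum(.data$nitrogen_kg) / 1000,
      .groups = "drop"
    )
  tibble::as_tibble(plots) |>
    dplyr::left_join(sums, by = "plot_id") |>
    dplyr::mutate(
      dplyr::across(c("n_stems", "biomass_mg", "carbon_mg", "nitrogen_mg"),
                    ~ dplyr::coalesce(.x, 0)),
      area_ha = plot_area_ha(.data$width_m, .data$length_m),
      carbon_mg_ha = .data$carbon_mg / .data$area_ha,
      nitrogen_mg_ha = .data$nitrogen_mg / .data$area_ha
    ) |>
    dplyr::select("plot_id", "lulc", "area_ha", "n_stems", "biomass_mg",
                  "carbon_mg", "nitrogen_mg", "carbon_mg_ha",
                  "nitrogen_mg_ha")
}

#' Per-class mean stock density with standard error
#'
#' The class density is the mean of the per-plot densities (Mg/ha) and its
#' standard error is the sample SD of the per-plot densities divided by
#' the square root of the number of plots. When every plot in a class has
#' the same area this equals the mean of plot stocks divided by the plot
#' area, the form in which such estimates are usually written; averaging
#' densities keeps the units coherent if plot sizes are ever mixed within
#' a class. Classes with a single plot get SE = 0 with a warning.
#'
#' @param plot_stocks Output of [plot_stocks()].
#' @param element `"C"`, `"N"` or `"both"` (default).
#' @param areas Optional LULC area table (`lulc`, `area_ha`); when given,
#'   total stocks `total_mg = mean density x class area` and
#'   `se_total_mg = SE x area` are appended.
#' @return A `stock_estimates` tibble with `lulc`, `element`, `n_plots`,
#'   `min_density`, `max_density`, `mean_density`, `se_density` (Mg/ha)
#'   and, with `areas`, `area_ha`, `total_mg`, `se_total_mg`.
#' @export
lulc_stock_estimates <- function(plot_stocks, element = "both",
                                 areas = NULL) {
  element <- match.arg(element, c("C", "N", "both"))
  stopifnot(is.data.frame(plot_stocks))
  if (!nrow(plot_stocks)) stop("no plot stocks supplied", call. = FALSE)
  long <- tibble::as_tibble(plot_stocks) |>
    dplyr::select("plot_id", "lulc", "carbon_mg_ha", "nitrogen_mg_ha") |>
    tidyr::pivot_longer(c("carbon_mg_ha", "nitrogen_mg_ha"),
                        names_to = "element", values_to = "density") |>
    dplyr::mutate(element = ifelse(.data$element == "carbon_mg_ha",
                                   "C", "N"))
  if (element != "both") {
    long <- dplyr::filter(long, .data$element == !!element)
  }
  est <- long |>
    dplyr::group_by(.data$lulc, .data$element) |>
    dplyr::summarise(
      n_plots = dplyr::n(),
      min_density = min(.data$density),
      max_density = max(.data$density),
      mean_density = mean(.data$density),
      se_density = se_mean(.data$density),
      .groups = "drop"
    )
  if (any(est$n_plots == 1L)) {
    warning("class(es) with a single plot: SE reported as 0", call. = FALSE)
  }
  if (!is.null(areas)) {
    est <- lulc_totals(est, areas)
  }
  class(est) <- c("stock_estimates", class(est))
  est
}

#' Scale class densities to total stocks by class area
#'
#' @param estimates A `stock_estimates` tibble (density part).
#' @param areas LULC area table with `lulc` and `area_ha` (and optionally
#'   `category`, carried through for [landscape_summary()]).
#' @return `estimates` with `area_ha`, `total_mg` (unrounded mean density
#'   times area) and `se_total_mg` (SE times area) appended.
#' @export
lulc_totals <- function(estimates, areas) {
  stopifnot(is.data.frame(estimates), is.data.frame(areas))
  if (!all(c("lulc", "area_ha") %in% names(areas))) {
    stop("area table needs 'lulc' and 'area_ha' columns", call. = FALSE)
  }
  if (any(areas$area_ha <= 0)) {
    stop("class areas must be positive", call. = FALSE)
  }
  unmapped <- setdiff(estimates$lulc, areas$lulc)
  if (length(unmapped)) {
    stop("no area for class(es): ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  keep <- intersect(c("lulc", "category", "area_ha"), names(areas))
  out <- estimates |>
    dplyr::left_join(dplyr::select(tibble::as_tibble(areas),
                                   dplyr::all_of(keep)), by = "lulc") |>
    dplyr::mutate(
      total_mg = .data$mean_density * .data$area_ha,
      se_total_mg = .data$se_density * .data$area_ha
    )
  class(out) <- unique(c("stock_estimates", class(out)))
  out
}

#' Landscape summary: category subtotals and grand totals
#'
#' Aggregates per-class total stocks into land-use category subtotals
#' (Forest land, Grassland, Cropland, Settlements, Agroforestry,
#' Plantation, ...) and a watershed grand total per element. Subtotal and
#' grand-total SEs are root-sum-of-squares of the class SEs, treating
#' classes as independent strata.
#'
#' @param estimates A `stock_estimates` tibble with `total_mg` (see
#'   [lulc_totals()]).
#' @param category_map Named character vector or data frame (`lulc`,
#'   `category`) mapping every class to exactly one category. Omit if
#'   `estimates` already carries a `category` column.
#' @return An object of class `landscape_summary`: list with `classes`
#'   (the input estimates with categories), `categories` (subtotal tibble)
#'   and `totals` (one row per element).
#' @export
landscape_summary <- function(estimates, category_map = NULL) {
  stopifnot(is.data.frame(estimates))
  if (!"total_mg" %in% names(estimates)) {
    stop("estimates lack total stocks; call lulc_totals() first",
         call. = FALSE)
  }
  est <- tibble::as_tibble(estimates)
  if (!is.null(category_map)) {
    if (is.data.frame(category_map)) {
      category_map <- setNames(category_map$category, category_map$lulc)
    }
    est$category <- unname(category_map[est$lulc])
  }
  if (!"category" %in% names(est)) {
    stop("no category mapping: supply category_map or a category column",
         call. = FALSE)
  }
  if (anyNA(est$category)) {
    stop("class(es) not mapped to a category: ",
         paste(unique(est$lulc[is.na(est$category)]), collapse = ", "),
         call. = FALSE)
  }
  if (!"se_total_mg" %in% names(est)) est$se_total_mg <- 0
  categories <- est |>
    dplyr::group_by(.data$category, .data$element) |>
    dplyr::summarise(
      n_classes = dplyr::n(),
      total_mg = sum(.data$total_mg),
      se_total_mg = sqrt(sum(.data$se_total_mg^2)),
      .groups = "drop"
    )
  totals <- categories |>
    dplyr::group_by(.data$element) |>
    dplyr::summarise(
      total_mg = sum(.data$total_mg),
      se_total_mg = sqrt(sum(.data$se_total_mg^2)),
      .groups = "drop"
    )
  structure(list(classes = est, categories = categories, totals = totals),
            class = "landscape_summary")
}

#' @export
print.landscape_summary <- function(x, ...) {
  cat("<landscape_summary>\n")
  for (i in seq_len(nrow(x$totals))) {
    cat(sprintf("  %s: %.2f +/- %.2f Mg over %d class(es)\n",
                x$totals$element[i], x$totals$total_mg[i],
                x$totals$se_total_mg[i],
                sum(x$classes$element == x$totals$element[i])))
  }
  invisible(x)
}

#' @method tidy landscape_summary
#' @export
tidy.landscape_summary <- function(x, ...) {
  x$categories
}

#' @method glance landscape_summary
#' @export
glance.landscape_summary <- function(x, ...) {
  tidyr::pivot_wider(x$totals, names_from = "element",
                     values_from = c("total_mg", "se_total_mg"))
}
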