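# CSV schemas (UTF-8, comma-separated, "." decimal, mandatory header)
# and the one-shot pipeline runner.

read_checked_csv <- function(path, required, what) {
  if (!file.exists(path)) {
    stop(what, " file not found: ", path, call. = FALSE)
  }
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(required, names(out))
  if (length(missing_cols)) {
    stop(what, " file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out
}

#' Read the pipeline's CSV inputs
#'
#' Schema-checked readers for the five tabular inputs: per-sample traits
#' (`species`, `carbon_pct`, `nitrogen_pct`), the per-species trait
#' summary (published-table layout), the stem census (`plot_id`,
#' `species`, `dbh_cm`, `height_m`, `wood_density_g_cm3`), the plot
#' register (`plot_id`, `lulc`, `width_m`, `length_m`) and the LULC area
#' table (`lulc`, `area_ha`, optionally `category`). Violations are
#' reported with the file and the offending column.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_traits_csv <- function(path) {
  out <- read_checked_csv(path, c("species", "carbon_pct", "nitrogen_pct"),
                          "traits sample")
  validate_wood_samples(out)
  out
}

#' @rdname read_traits_csv
#' @export
read_traits_summary_csv <- function(path) {
  read_checked_csv(path, c("species", "n_samples", "c_mean", "c_se",
                           "n_mean", "n_se"),
                   "traits summary")
}

#' @rdname read_traits_csv
#' @export
read_census_csv <- function(path) {
  out <- read_checked_csv(path, c("plot_id", "species", "dbh_cm"),
                          "census")
  validate_trees(out)
  out
}

#' @rdname read_traits_csv
#' @export
read_plots_csv <- function(path) {
  out <- read_checked_csv(path, c("plot_id", "lulc", "width_m",
                                  "length_m"), "plot register")
  validate_plots(out)
  out
}

#' @rdname read_traits_csv
#' @export
read_area_csv <- function(path) {
  read_checked_csv(path, c("lulc", "area_ha"), "area table")
}

#' @rdname read_traits_csv
#' @export
read_tier_errors_csv <- function(path) {
  read_checked_csv(path, c("lulc", "error_050_pct"), "tier errors")
}

#' Read and write an allometric-model registry as YAML
#'
#' The registry file is a list of model entries:
#' ```yaml
#' default: pantropical
#' models:
#'   - model_id: pantropical
#'     form: power_product
#'     coefficients: {a: 0.0673, b: 0.976}
#'     dbh_range: [5, 120]
#'   - model_id: palm
#'     form: linear_combination
#'     coefficients: {a: 0.0, b: 2.0, c: 0.8}
#'     species: [Phoenix reclinata, Borassus flabellifer]
#'     dbh_range: [5, 60]
#' ```
#' Schema violations are reported with the entry index and field.
#'
#' @param path YAML file path.
#' @param registry A [model_registry()] (for writing).
#' @return `read_registry()` returns a [model_registry()];
#'   `write_registry()` returns `path` invisibly.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) {
    stop("registry file not found: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw$models) || !length(raw$models)) {
    stop("registry file ", path, " has no 'models' entries",
         call. = FALSE)
  }
  models <- lapply(seq_along(raw$models), function(i) {
    e <- raw$models[[i]]
    for (field in c("model_id", "form", "coefficients")) {
      if (is.null(e[[field]])) {
        stop("registry entry ", i, " is missing field '", field, "'",
             call. = FALSE)
      }
    }
    allometric_model(
      model_id = e$model_id, form = e$form,
      coefficients = unlist(e$coefficients),
      species = e$species %||% character(),
      lulc = e$lulc %||% character(),
      dbh_range = unlist(e$dbh_range %||% c(5, 100))
    )
  })
  model_registry(models, default = raw$default)
}

#' @rdname read_registry
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "model_registry"))
  entries <- lapply(unname(registry$models), function(m) {
    e <- list(model_id = m$model_id, form = m$form,
              coefficients = as.list(m$coefficients),
              dbh_range = m$dbh_range)
    if (length(m$species)) e$species <- m$species
    if (length(m$lulc)) e$lulc <- m$lulc
    e
  })
  yaml::write_yaml(list(default = registry$default, models = entries),
                   path)
  invisible(path)
}

#' The default allometric registry
#'
#' A generic pantropical `power_product` model (a = 0.0673, b = 0.976 on
#' rho * D^2 * H) as the default and as a per-LULC entry for each class
#' of the study design, plus a palm-style `linear_combination` model for
#' *Phoenix reclinata* and *Borassus flabellifer*. The per-LULC
#' coefficients are placeholders meant to be overwritten with locally
#' fitted equations (or rescaled by [calibrate_registry()]); they are not
#' fitted values.
#'
#' @param lulc Classes to create per-LULC entries for.
#' @return A [model_registry()].
#' @export
default_registry <- function(lulc = generate_area_table()$lulc) {
  per_class <- lapply(lulc, function(cl)
    allometric_model(paste0("pantropical::", cl), "power_product",
                     c(a = 0.0673, b = 0.976), lulc = cl,
                     dbh_range = c(5, 120)))
  model_registry(c(
    list(allometric_model("pantropical", "power_product",
                          c(a = 0.0673, b = 0.976),
                          dbh_range = c(5, 120)),
         allometric_model("palm", "linear_combination",
                          c(a = 0, b = 2, c = 0.8),
                          species = c("Phoenix reclinata",
                                      "Borassus flabellifer"),
                          dbh_range = c(5, 60))),
    per_class), default = "pantropical")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full stock-accounting pipeline over CSV inputs
#'
#' Reads the inputs, resolves biomass and fractions, aggregates stocks to
#' plot, class and landscape level, runs the Tier 1 coefficient
#' comparison, optionally renders per-class stock maps, and writes every
#' artifact to `out_dir`. Deterministic given inputs and seed; a
#' `run_log.json` records the package version, seed and an MD5 checksum
#' of every input.
#'
#' @param traits Path to the per-species trait summary CSV, or a
#'   `traits_table`.
#' @param census Path to the census CSV, or a data frame.
#' @param plots Path to the plot register CSV, or a data frame.
#' @param areas Path to the LULC area CSV, or a data frame; needs a
#'   `category` column for the landscape summary.
#' @param registry Path to a registry YAML, or a [model_registry()];
#'   default [default_registry()].
#' @param element `"C"`, `"N"` or `"both"`.
#' @param weighting Overall-mean weighting for [traits_table()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing and returns the results only.
#' @param map_resolution Cell size in m for the rendered stock maps;
#'   `NULL` skips map rendering.
#' @param seed Integer seed (controls only the class-map layout; the
#'   estimation itself is deterministic).
#' @return Invisibly, a list with `traits`, `tree_stocks`, `plot_stocks`,
#'   `estimates`, `summary`, `tier`, `ivi`, `density`, and (with maps)
#'   `class_map` and `stock_maps`.
#' @export
run_pipeline <- function(census, plots, areas,
                         traits = savstocks_example("stem_wood_traits.csv"),
                         registry = default_registry(),
                         element = c("both", "C", "N"),
                         weighting = c("species", "samples"),
                         out_dir = NULL, map_resolution = NULL, seed = 1) {
  element <- match.arg(element)
  weighting <- match.arg(weighting)
  inputs <- list(traits = traits, census = census, plots = plots,
                 areas = areas, registry = registry)
  paths <- Filter(function(x) is.character(x) && length(x) == 1,
                  inputs)

  if (!inherits(traits, "traits_table")) {
    if (is.character(traits)) traits <- read_traits_summary_csv(traits)
    traits <- traits_table(traits, weighting = weighting)
  }
  if (is.character(census)) census <- read_census_csv(census)
  if (is.character(plots)) plots <- read_plots_csv(plots)
  if (is.character(areas)) areas <- read_area_csv(areas)
  if (is.character(registry)) registry <- read_registry(registry)
  validate_plots(plots)
  validate_trees(census, plots)
  unknown <- setdiff(unique(plots$lulc), areas$lulc)
  if (length(unknown)) {
    stop("plot register uses LULC class(es) missing from the area ",
         "table: ", paste(unknown, collapse = ", "), call. = FALSE)
  }

  stems <- predict_biomass(census, registry, plots = plots) |>
    tree_stocks(traits)
  per_plot <- plot_stocks(stems, plots)
  estimates <- lulc_stock_estimates(per_plot, element = element,
                                    areas = areas)
  summary <- if ("category" %in% names(areas))
    landscape_summary(estimates) else NULL
  tier <- tier_report(tree_stocks = stems)
  ivi <- importance_value_index(census, plots)
  density <- stem_density(census, plots)

  result <- list(traits = traits, tree_stocks = stems,
                 plot_stocks = per_plot, estimates = estimates,
                 summary = summary, tier = tier, ivi = ivi,
                 density = density)

  if (!is.null(map_resolution)) {
    cmap <- generate_class_map(areas, resolution = map_resolution,
                               seed = seed)
    elements <- if (element == "both") c("C", "N") else element
    result$class_map <- cmap
    result$stock_maps <- lapply(setNames(elements, elements), function(el)
      write_stock_map_values(
        cmap, dplyr::filter(estimates, .data$element == el)))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_estimates_csv(estimates,
                        file.path(out_dir, "stock_estimates.csv"))
    readr::write_csv(tier, file.path(out_dir, "tier_report.csv"))
    readr::write_csv(ivi, file.path(out_dir, "ivi.csv"))
    readr::write_csv(density, file.path(out_dir, "stem_density.csv"))
    readr::write_csv(per_plot, file.path(out_dir, "plot_stocks.csv"))
    if (!is.null(summary)) {
      readr::write_csv(summary$categories,
                       file.path(out_dir, "landscape_categories.csv"))
      readr::write_csv(summary$totals,
                       file.path(out_dir, "landscape_totals.csv"))
    }
    if (!is.null(result$stock_maps)) {
      write_ascii_grid(result$class_map,
                       file.path(out_dir, "class_map.asc"))
      for (el in names(result$stock_maps)) {
        write_ascii_grid(result$stock_maps[[el]],
                         file.path(out_dir,
                                   paste0("stock_map_", el, ".asc")))
      }
    }
    log <- list(
      package = "savstocks",
      version = as.character(utils::packageVersion("savstocks")),
      seed = seed, element = element, weighting = weighting,
      input_md5 = as.list(vapply(paths, function(p)
        unname(tools::md5sum(p)), character(1)))
    )
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(result)
}

#' Write per-class stock estimates with table-style formatting
#'
#' Writes the estimates with the full-precision columns plus 2-decimal
#' display columns matching the layout stock tables are usually printed
#' in.
#'
#' @param estimates A `stock_estimates` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_estimates_csv <- function(estimates, path) {
  out <- tibble::as_tibble(estimates) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                ~ round(.x, 2),
                                .names = "{.col}_2dp"))
  readr::write_csv(out, path)
  invisible(path)
}
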