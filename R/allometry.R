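#' Define an allometric biomass model
#'
#' An allometric model maps field measurements of a standing tree to its
#' oven-dry aboveground biomass in kg. Three functional forms cover the
#' equations in common use for savannah trees and for palms:
#'
#' * `power_product`: B = a * (rho * D^2 * H)^b — the pantropical form with
#'   wood density rho (g/cm3), DBH D (cm) and height H (m);
#' * `power_dbh`: B = a * D^b — diameter-only models;
#' * `linear_combination`: B = a + b*D + c*D^2 — the palm-style form, since
#'   palm stems violate D^2 H scaling.
#'
#' @param model_id Unique model name.
#' @param form One of `"power_product"`, `"power_dbh"`,
#'   `"linear_combination"`.
#' @param coefficients Named numeric vector; `a`, `b` (and `c` for the
#'   linear form) as required by `form`.
#' @param species Character vector of species the model applies to
#'   (species routing takes precedence over LULC routing).
#' @param lulc Character vector of LULC classes the model applies to.
#' @param dbh_range Length-2 numeric, the DBH validity interval in cm;
#'   predictions outside it extrapolate with a warning.
#' @return An object of class `allometric_model`.
#' @export
#' @examples
#' m <- allometric_model("pantropical", "power_product",
#'                       c(a = 0.0673, b = 0.976))
#' estimate_biomass(m, dbh = 20, height = 10, wood_density = 0.6)
allometric_model <- function(model_id, form, coefficients,
                             species = character(), lulc = character(),
                             dbh_range = c(5, 100)) {
  form <- match.arg(form,
                    c("power_product", "power_dbh", "linear_combination"))
  need <- switch(form,
                 power_product = c("a", "b"),
                 power_dbh = c("a", "b"),
                 linear_combination = c("a", "b", "c"))
  coefficients <- unlist(coefficients)
  if (!all(need %in% names(coefficients))) {
    stop("form '", form, "' needs coefficients ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(coefficients))) {
    stop("coefficients must be finite", call. = FALSE)
  }
  stopifnot(length(dbh_range) == 2L, dbh_range[1] > 0,
            dbh_range[2] > dbh_range[1])
  structure(
    list(model_id = as.character(model_id), form = form,
         coefficients = coefficients[need],
         species = as.character(species), lulc = as.character(lulc),
         dbh_range = as.numeric(dbh_range)),
    class = "allometric_model"
  )
}

#' @export
print.allometric_model <- function(x, ...) {
  eq <- switch(x$form,
    power_product = "B = a * (rho * D^2 * H)^b",
    power_dbh = "B = a * D^b",
    linear_combination = "B = a + b*D + c*D^2")
  cat("<allometric_model> ", x$model_id, ": ", eq, "\n", sep = "")
  cat("  coefficients:", paste(names(x$coefficients),
      signif(x$coefficients, 6), sep = " = ", collapse = ", "), "\n")
  if (length(x$species)) cat("  species:", paste(x$species, collapse = ", "), "\n")
  if (length(x$lulc)) cat("  lulc:", paste(x$lulc, collapse = ", "), "\n")
  cat("  DBH validity: [", x$dbh_range[1], ",", x$dbh_range[2], "] cm\n")
  invisible(x)
}

#' Build a registry of allometric models
#'
#' A registry holds the models available to the pipeline and resolves, for
#' every (species, LULC) pair, exactly one model by routing order:
#' species-specific first (e.g. the palm model for *Phoenix reclinata* and
#' *Borassus flabellifer*), then LULC-specific, then the default model.
#'
#' @param ... [allometric_model()] objects.
#' @param default The `model_id` of the model used when nothing more
#'   specific matches; defaults to the first model with no species/LULC
#'   restriction, or the single model if only one is given.
#' @return An object of class `model_registry`.
#' @seealso [read_registry()] for loading a registry from YAML.
#' @export
model_registry <- function(..., default = NULL) {
  models <- list(...)
  if (length(models) == 1L && is.list(models[[1]]) &&
      !inherits(models[[1]], "allometric_model")) {
    models <- models[[1]]
  }
  if (!length(models)) stop("registry needs at least one model", call. = FALSE)
  if (!all(vapply(models, inherits, logical(1), "allometric_model"))) {
    stop("all registry entries must be allometric_model objects",
         call. = FALSE)
  }
  ids <- vapply(models, `[[`, character(1), "model_id")
  if (anyDuplicated(ids)) stop("duplicate model_id in registry", call. = FALSE)
  names(models) <- ids
  if (is.null(default)) {
    unrestricted <- ids[vapply(models, function(m)
      !length(m$species) && !length(m$lulc), logical(1))]
    default <- if (length(unrestricted)) unrestricted[1] else ids[1]
  }
  if (!default %in% ids) {
    stop("default model '", default, "' not in registry", call. = FALSE)
  }
  structure(list(models = models, default = default),
            class = "model_registry")
}

#' @export
print.model_registry <- function(x, ...) {
  cat("<model_registry> ", length(x$models), " model(s), default = '",
      x$default, "'\n", sep = "")
  for (m in x$models) print(m)
  invisible(x)
}

#' Resolve the allometric model for a (species, LULC) pair
#'
#' @param registry A [model_registry()].
#' @param species Species name (scalar).
#' @param lulc LULC class name (scalar).
#' @return The matching [allometric_model()]; species routing beats LULC
#'   routing beats the default.
#' @export
select_model <- function(registry, species, lulc) {
  stopifnot(inherits(registry, "model_registry"))
  sp <- canonical_species(species)
  for (m in registry$models) {
    if (sp %in% canonical_species(m$species)) return(m)
  }
  for (m in registry$models) {
    if (!length(m$species) && lulc %in% m$lulc) return(m)
  }
  registry$models[[registry$default]]
}

#' Estimate oven-dry aboveground biomass of one or more stems
#'
#' Evaluates an allometric model; vectorised over the measurements.
#'
#' @param model An [allometric_model()].
#' @param dbh DBH in cm (census threshold is 5 cm).
#' @param height Total tree height in m (required for `power_product`).
#' @param wood_density Wood density in g/cm3 (required for
#'   `power_product`; accepted range 0.1–1.5).
#' @return Biomass in kg dry matter (non-negative). A warning (not an
#'   error) is raised when any DBH lies outside the model's validity range.
#' @export
estimate_biomass <- function(model, dbh, height = NULL, wood_density = NULL) {
  stopifnot(inherits(model, "allometric_model"))
  if (any(!is.finite(dbh)) || any(dbh <= 0)) {
    stop("dbh must be positive", call. = FALSE)
  }
  if (any(dbh < model$dbh_range[1] | dbh > model$dbh_range[2])) {
    warning("DBH outside validity range [", model$dbh_range[1], ", ",
            model$dbh_range[2], "] cm of model '", model$model_id,
            "'; extrapolating", call. = FALSE)
  }
  cf <- model$coefficients
  b <- switch(model$form,
    power_product = {
      if (is.null(height) || is.null(wood_density)) {
        stop("power_product form needs height and wood_density",
             call. = FALSE)
      }
      if (any(!is.finite(height)) || any(height <= 0)) {
        stop("height must be positive", call. = FALSE)
      }
      if (any(wood_density < 0.1 | wood_density > 1.5)) {
        stop("wood_density must lie in [0.1, 1.5] g/cm3", call. = FALSE)
      }
      cf[["a"]] * (wood_density * dbh^2 * height)^cf[["b"]]
    },
    power_dbh = cf[["a"]] * dbh^cf[["b"]],
    linear_combination = cf[["a"]] + cf[["b"]] * dbh + cf[["c"]] * dbh^2
  )
  if (any(b < 0)) {
    stop("model '", model$model_id, "' produced negative biomass",
         call. = FALSE)
  }
  unname(b)
}

#' Add model-resolved biomass to a tree census
#'
#' Routes every stem through [select_model()] and evaluates the resolved
#' model, returning the census with `model_id` and `biomass_kg` columns.
#'
#' @param trees Census data frame with columns `plot_id`, `species`,
#'   `dbh_cm`, `height_m`, `wood_density_g_cm3`, plus `lulc` (or joinable
#'   via `plots`).
#' @param registry A [model_registry()].
#' @param plots Optional plot register (columns `plot_id`, `lulc`) used to
#'   attach the LULC class when `trees` lacks an `lulc` column.
#' @return `trees` as a tibble with `model_id` and `biomass_kg` appended.
#' @export
predict_biomass <- function(trees, registry, plots = NULL) {
  stopifnot(is.data.frame(trees), inherits(registry, "model_registry"))
  trees <- tibble::as_tibble(trees)
  if (!"lulc" %in% names(trees)) {
    if (is.null(plots)) {
      stop("trees need an 'lulc' column or a plot register", call. = FALSE)
    }
    trees <- dplyr::left_join(trees,
      dplyr::select(tibble::as_tibble(plots), "plot_id", "lulc"),
      by = "plot_id")
    if (anyNA(trees$lulc)) {
      stop("some trees reference plot_ids missing from the register",
           call. = FALSE)
    }
  }
  trees |>
    dplyr::mutate(
      .group = paste(canonical_species(.data$species), .data$lulc,
                     sep = "\r")) |>
    dplyr::group_by(.data$.group) |>
    dplyr::group_modify(function(d, key) {
      m <- select_model(registry, d$species[1], d$lulc[1])
      d$model_id <- m$model_id
      d$biomass_kg <- estimate_biomass(m, d$dbh_cm, d$height_m,
                                       d$wood_density_g_cm3)
      d
    }) |>
    dplyr::ungroup() |>
    dplyr::select(-".group")
}
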