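#' Plot area in hectares
#'
#' @param width,length Plot dimensions in metres. Vectorised.
#' @return Area in ha (`width * length / 10000`). The designs in common
#'   use are 30 x 30 m (0.09 ha), 100 x 100 m (1 ha) and 10 x 20 m
#'   (0.02 ha), but any positive dimensions are accepted.
#' @export
plot_area_ha <- function(width, length) {
  if (any(!is.finite(width)) || any(!is.finite(length)) ||
      any(width <= 0) || any(length <= 0)) {
    stop("plot dimensions must be positive", call. = FALSE)
  }
  width * length / 1e4
}

#' Basal area of a stem from its DBH
#'
#' @param dbh DBH in cm. Vectorised.
#' @return Cross-sectional area at breast height in m2:
#'   `pi * (dbh / 200)^2`.
#' @export
basal_area <- function(dbh) {
  if (any(!is.finite(dbh)) || any(dbh <= 0)) {
    stop("dbh must be positive", call. = FALSE)
  }
  pi * (dbh / 200)^2
}

validate_plots <- function(plots) {
  req <- c("plot_id", "lulc", "width_m", "length_m")
  missing_cols <- setdiff(req, names(plots))
  if (length(missing_cols)) {
    stop("plot register missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(plots$plot_id)) {
    stop("duplicate plot_id in plot register", call. = FALSE)
  }
  plot_area_ha(plots$width_m, plots$length_m)
  invisible(plots)
}

validate_trees <- function(trees, plots = NULL) {
  req <- c("plot_id", "species", "dbh_cm")
  missing_cols <- setdiff(req, names(trees))
  if (length(missing_cols)) {
    stop("census missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(trees) && any(trees$dbh_cm < 5)) {
    stop("census contains stems below the 5 cm DBH threshold",
         call. = FALSE)
  }
  if ("height_m" %in% names(trees) && nrow(trees) &&
      any(!is.na(trees$height_m) & trees$height_m <= 0)) {
    stop("tree heights must be positive", call. = FALSE)
  }
  if (!is.null(plots)) {
    orphan <- setdiff(trees$plot_id, plots$plot_id)
    if (length(orphan)) {
      stop("census references unknown plot_id(s): ",
           paste(head(orphan, 5), collapse = ", "), call. = FALSE)
    }
  }
  invisible(trees)
}

#' Stem density per LULC class
#'
#' Pooled-ratio estimator: total stems in the class divided by the total
#' sampled area of the class, in stems per hectare. Classes whose plots
#' hold no stems get density 0.
#'
#' @param trees Census data frame (`plot_id`, `species`, `dbh_cm`, ...).
#' @param plots Plot register (`plot_id`, `lulc`, `width_m`, `length_m`).
#' @param lulc Optional class name(s) to restrict to.
#' @return A tibble with `lulc`, `n_plots`, `area_sampled_ha`, `n_stems`,
#'   `stems_per_ha`.
#' @export
stem_density <- function(trees, plots, lulc = NULL) {
  validate_plots(plots)
  validate_trees(trees, plots)
  plots <- tibble::as_tibble(plots)
  if (!is.null(lulc)) {
    plots <- dplyr::filter(plots, .data$lulc %in% !!lulc)
    if (!nrow(plots)) stop("no plots of class ", paste(lulc, collapse = ", "),
                           call. = FALSE)
  }
  counts <- tibble::as_tibble(trees) |>
    dplyr::count(.data$plot_id, name = "n_stems")
  plots |>
    dplyr::left_join(counts, by = "plot_id") |>
    dplyr::mutate(
      n_stems = dplyr::coalesce(.data$n_stems, 0L),
      area_ha = plot_area_ha(.data$width_m, .data$length_m)) |>
    dplyr::group_by(.data$lulc) |>
    dplyr::summarise(
      n_plots = dplyr::n(),
      area_sampled_ha = sum(.data$area_ha),
      n_stems = sum(.data$n_stems),
      stems_per_ha = .data$n_stems / .data$area_sampled_ha,
      .groups = "drop"
    )
}

#' Importance Value Index per species
#'
#' The IVI of a species is the sum of its relative density (share of
#' stems), relative frequency (share of plot occurrences) and relative
#' dominance (share of basal area), each expressed in percent, so the IVI
#' column sums to 300 over species.
#'
#' @inheritParams stem_density
#' @return A tibble with `species`, `n_stems`, `n_plots_present`,
#'   `relative_density`, `relative_frequency`, `relative_dominance` and
#'   `ivi`, sorted by decreasing IVI (alphabetical tie-break).
#' @export
importance_value_index <- function(trees, plots) {
  validate_plots(plots)
  validate_trees(trees, plots)
  if (nrow(trees) == 0L) {
    stop("IVI needs at least one stem", call. = FALSE)
  }
  trees <- tibble::as_tibble(trees)
  per_species <- trees |>
    dplyr::mutate(ba = basal_area(.data$dbh_cm)) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n_stems = dplyr::n(),
      n_plots_present = dplyr::n_distinct(.data$plot_id),
      ba_total = sum(.data$ba),
      .groups = "drop"
    )
  per_species |>
    dplyr::mutate(
      relative_density = 100 * .data$n_stems / sum(.data$n_stems),
      relative_frequency =
        100 * .data$n_plots_present / sum(.data$n_plots_present),
      relative_dominance = 100 * .data$ba_total / sum(.data$ba_total),
      ivi = .data$relative_density + .data$relative_frequency +
        .data$relative_dominance
    ) |>
    dplyr::select(-"ba_total") |>
    dplyr::arrange(dplyr::desc(.data$ivi), .data$species)
}
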