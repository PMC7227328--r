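# ggplot2 methods for the main result types.

#' Plot per-species C or N fraction summaries
#'
#' Point-range plot of the per-species mean fraction with +/- 1 SE bars,
#' species ordered by mean, with the overall mean as a dashed reference
#' line (for carbon this sits next to the IPCC Tier 1 default of 47%).
#'
#' @param object A [traits_table()].
#' @param element `"C"` or `"N"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot traits_table
#' @export
autoplot.traits_table <- function(object, element = c("C", "N"), ...) {
  element <- match.arg(element)
  d <- object$species
  if (element == "C") {
    d <- dplyr::mutate(d, mean = .data$c_mean, se = .data$c_se)
    lab <- "Carbon content (% dry matter)"
  } else {
    d <- dplyr::mutate(d, mean = .data$n_mean, se = .data$n_se)
    lab <- "Nitrogen content (% dry matter)"
  }
  overall <- frac_to_pct(overall_mean_fraction(object, element))
  ggplot2::ggplot(d, ggplot2::aes(
      x = stats::reorder(.data$species, .data$mean), y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - .data$se, ymax = .data$mean + .data$se)) +
    ggplot2::geom_hline(yintercept = overall, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = lab) +
    ggplot2::theme_minimal()
}

#' Plot per-class stock densities with standard errors
#'
#' @param object A `stock_estimates` tibble (see
#'   [lulc_stock_estimates()]).
#' @param ... Unused.
#' @return A ggplot object, faceted by element when both are present.
#' @method autoplot stock_estimates
#' @export
autoplot.stock_estimates <- function(object, ...) {
  d <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(
      x = stats::reorder(.data$lulc, .data$mean_density),
      y = .data$mean_density)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(.data$mean_density - .data$se_density, 0),
      ymax = .data$mean_density + .data$se_density), width = 0.25) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Mean stock density (Mg/ha)") +
    ggplot2::theme_minimal()
  if (length(unique(d$element)) > 1L) {
    p <- p + ggplot2::facet_wrap(~element, scales = "free_x")
  }
  p
}

#' Plot fixed-coefficient conversion errors per class
#'
#' Dumbbell-style comparison of the relative error committed by the 0.5
#' and 0.47 biomass-to-carbon coefficients in each LULC class.
#'
#' @param object A `tier_report` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tier_report
#' @export
autoplot.tier_report <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::select("lulc", "error_050_pct", "error_047_pct") |>
    tidyr::pivot_longer(-"lulc", names_to = "coefficient",
                        values_to = "error_pct") |>
    dplyr::mutate(coefficient = ifelse(
      .data$coefficient == "error_050_pct", "0.50", "0.47"))
  ggplot2::ggplot(d, ggplot2::aes(
      x = .data$error_pct, y = .data$lulc,
      colour = .data$coefficient)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = "Relative error of fixed coefficient (%)",
                  y = NULL, colour = "Coefficient") +
    ggplot2::theme_minimal()
}

#' Plot a class map or stock map
#'
#' @param object A `class_map` or `stock_map`.
#' @param ... Unused.
#' @return A ggplot raster of the grid; classes as discrete fill,
#'   densities as a continuous gradient.
#' @method autoplot class_map
#' @export
autoplot.class_map <- function(object, ...) {
  d <- map_to_tibble(object)
  d$lulc <- factor(object$classes[d$value], levels = object$classes)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y,
                                  fill = .data$lulc)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "LULC") +
    ggplot2::theme_void()
}

#' @rdname autoplot.class_map
#' @method autoplot stock_map
#' @export
autoplot.stock_map <- function(object, ...) {
  d <- map_to_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Mg/ha") +
    ggplot2::theme_void()
}

map_to_tibble <- function(map) {
  v <- map$values
  d <- tibble::tibble(
    x = rep(seq_len(ncol(v)), each = nrow(v)),
    y = rep(rev(seq_len(nrow(v))), times = ncol(v)),
    value = as.vector(v)
  )
  d[!is.na(d$value), ]
}
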