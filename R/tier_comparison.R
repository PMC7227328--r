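#' Effective biomass-to-carbon fraction of a stratum
#'
#' The biomass-weighted carbon fraction actually realised in a class:
#' total carbon stock divided by total biomass. This is the quantity a
#' fixed Tier 1 conversion coefficient stands in for, and the right
#' weighting because class carbon density is itself a biomass-weighted
#' sum.
#'
#' @param tree_stocks Output of [tree_stocks()], optionally pre-filtered;
#'   with `by = "lulc"` an `lulc` column is required.
#' @param by `NULL` for a single pooled fraction, or `"lulc"` for one
#'   fraction per class.
#' @return A tibble with `effective_fraction` (and `lulc` when grouped).
#' @export
effective_fraction <- function(tree_stocks, by = "lulc") {
  stopifnot(is.data.frame(tree_stocks))
  req <- c("biomass_kg", "carbon_kg")
  if (!all(req %in% names(tree_stocks))) {
    stop("need biomass_kg and carbon_kg columns (run tree_stocks())",
         call. = FALSE)
  }
  grouped <- if (is.null(by)) tibble::as_tibble(tree_stocks) else
    dplyr::group_by(tibble::as_tibble(tree_stocks),
                    dplyr::across(dplyr::all_of(by)))
  out <- grouped |>
    dplyr::summarise(
      biomass_kg = sum(.data$biomass_kg),
      carbon_kg = sum(.data$carbon_kg),
      .groups = "drop"
    )
  if (any(out$biomass_kg <= 0)) {
    stop("zero total biomass: effective fraction undefined", call. = FALSE)
  }
  out |>
    dplyr::mutate(effective_fraction = .data$carbon_kg / .data$biomass_kg) |>
    dplyr::select(-"biomass_kg", -"carbon_kg")
}

#' Relative error of a fixed conversion coefficient
#'
#' Percentage error committed when a fixed biomass-to-carbon coefficient
#' replaces the in-situ effective fraction:
#' `100 * (coefficient / effective_fraction - 1)`. Positive values are
#' overestimates. Vectorised over both arguments.
#'
#' @param effective_fraction In-situ effective carbon fraction
#'   (proportion, > 0).
#' @param coefficient Fixed coefficient (e.g. 0.47 for IPCC Tier 1, 0.5
#'   for the common alternative).
#' @return Relative error in percent.
#' @export
coefficient_error <- function(effective_fraction, coefficient) {
  if (any(!is.finite(effective_fraction)) || any(effective_fraction <= 0)) {
    stop("effective_fraction must be positive", call. = FALSE)
  }
  100 * (coefficient / effective_fraction - 1)
}

#' Recover an effective fraction from a coefficient's relative error
#'
#' Algebraic inverse of [coefficient_error()]:
#' `fraction = coefficient / (1 + error_pct / 100)`. Used to re-derive the
#' in-situ fraction implied by a published error percentage and evaluate a
#' different coefficient against it.
#'
#' @param coefficient The fixed coefficient the error refers to.
#' @param error_pct Relative error in percent (> −100).
#' @return The implied effective fraction (proportion).
#' @export
invert_error <- function(coefficient, error_pct) {
  if (any(!is.finite(error_pct)) || any(error_pct <= -100)) {
    stop("error_pct must be greater than -100", call. = FALSE)
  }
  coefficient / (1 + error_pct / 100)
}

#' Tier 1 coefficient error report per LULC class
#'
#' Compares fixed biomass-to-carbon coefficients (0.5 as used in several
#' pantropical maps, and the IPCC Tier 1 default 0.47) against each
#' class's effective carbon fraction. Two input routes:
#'
#' * from stem-level stocks (`tree_stocks`), the effective fraction is
#'   computed per class and both coefficient errors evaluated against it;
#' * from a published pair of error percentages (`errors_050` plus
#'   optionally `errors_047`), the fraction is recovered by
#'   [invert_error()] from the 0.5 error and 0.47 re-evaluated. When a
#'   printed 0.47 error is supplied it is checked against the exact
#'   algebraic link `e47 = 100*(0.94*(1 + e50/100) - 1)`; pairs that
#'   violate it beyond `tol_pp` are flagged inconsistent rather than
#'   silently accepted.
#'
#' @param tree_stocks Output of [tree_stocks()] with an `lulc` column.
#' @param errors_050 Data frame with `lulc`, `error_050_pct` and
#'   optionally `error_047_pct` (published values).
#' @param tol_pp Tolerance (percentage points) for the consistency check
#'   of published pairs.
#' @return A `tier_report` tibble: `lulc`, `effective_fraction`,
#'   `error_050_pct`, `error_047_pct` and, for published pairs,
#'   `reported_047_pct` and `consistent`.
#' @export
#' @examples
#' published <- read_tier_errors_csv(
#'   savstocks_example("tier1_coefficient_errors.csv"))
#' tier_report(errors_050 = published)
tier_report <- function(tree_stocks = NULL, errors_050 = NULL,
                        tol_pp = 0.02) {
  if (is.null(tree_stocks) == is.null(errors_050)) {
    stop("supply exactly one of tree_stocks or errors_050", call. = FALSE)
  }
  if (!is.null(tree_stocks)) {
    frac <- effective_fraction(tree_stocks, by = "lulc")
    out <- frac |>
      dplyr::mutate(
        error_050_pct = coefficient_error(.data$effective_fraction, 0.5),
        error_047_pct = coefficient_error(.data$effective_fraction, 0.47)
      )
  } else {
    stopifnot(is.data.frame(errors_050))
    if (!all(c("lulc", "error_050_pct") %in% names(errors_050))) {
      stop("errors_050 needs 'lulc' and 'error_050_pct' columns",
           call. = FALSE)
    }
    out <- tibble::as_tibble(errors_050)
    if ("error_047_pct" %in% names(out)) {
      out <- dplyr::rename(out, reported_047_pct = "error_047_pct")
    }
    out <- out |>
      dplyr::mutate(
        effective_fraction = invert_error(0.5, .data$error_050_pct),
        error_047_pct = coefficient_error(.data$effective_fraction, 0.47)
      )
    if ("reported_047_pct" %in% names(out)) {
      out <- dplyr::mutate(out,
        consistent =
          abs(.data$error_047_pct - .data$reported_047_pct) <= tol_pp)
    }
    out <- dplyr::relocate(out, "effective_fraction", .after = "lulc")
  }
  class(out) <- c("tier_report", class(out))
  out
}
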