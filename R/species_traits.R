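#' Summarize per-sample wood C/N measurements by species
#'
#' Collapses raw stem-wood samples (one row per sample, C and N fractions of
#' dry matter in percent) to per-species summary statistics: n, min, max,
#' mean and standard error of the mean for carbon, nitrogen and the
#' per-sample C/N ratio. This reproduces the layout of a published
#' species-traits table where each cell is "mean (SE)".
#'
#' The SE is the sample standard deviation (n − 1 denominator) divided by
#' the square root of n; species with a single sample get SE = 0 with a
#' warning, so the summary stays total.
#'
#' @param samples Data frame with columns `species`, `carbon_pct`,
#'   `nitrogen_pct` (fractions of dry matter, in percent) and optionally
#'   `dbh_cm`.
#' @param species Optional single species name; if given, `samples` must
#'   contain only that species (mixed input is an error).
#' @return A tibble with one row per species and columns `species`,
#'   `n_samples`, `c_min`, `c_max`, `c_mean`, `c_se`, `n_min`, `n_max`,
#'   `n_mean`, `n_se`, `cn_mean`, `cn_se` (C/N stats in percent of dry
#'   matter, C/N ratio dimensionless).
#' @export
#' @examples
#' samples <- data.frame(
#'   species = "Vitelaria paradoxa",
#'   carbon_pct = c(44, 46, 48),
#'   nitrogen_pct = c(0.20, 0.22, 0.24)
#' )
#' summarize_species(samples)
summarize_species <- function(samples, species = NULL) {
  stopifnot(is.data.frame(samples))
  if (nrow(samples) == 0L) {
    stop("no wood samples supplied", call. = FALSE)
  }
  req <- c("species", "carbon_pct", "nitrogen_pct")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols)) {
    stop("samples are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_wood_samples(samples)
  if (!is.null(species)) {
    keys <- unique(canonical_species(samples$species))
    if (length(keys) > 1L || keys != canonical_species(species)) {
      stop("samples contain species other than '", species, "'",
           call. = FALSE)
    }
  }
  if (any(table(canonical_species(samples$species)) == 1L)) {
    warning("species with a single sample: SE reported as 0", call. = FALSE)
  }
  samples |>
    dplyr::mutate(cn_ratio = .data$carbon_pct / .data$nitrogen_pct) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      c_min = min(.data$carbon_pct),
      c_max = max(.data$carbon_pct),
      c_mean = mean(.data$carbon_pct),
      c_se = se_mean(.data$carbon_pct),
      n_min = min(.data$nitrogen_pct),
      n_max = max(.data$nitrogen_pct),
      n_mean = mean(.data$nitrogen_pct),
      n_se = se_mean(.data$nitrogen_pct),
      cn_mean = mean(.data$cn_ratio),
      cn_se = se_mean(.data$cn_ratio),
      .groups = "drop"
    )
}

validate_wood_samples <- function(samples) {
  c_frac <- samples$carbon_pct / 100
  n_frac <- samples$nitrogen_pct / 100
  if (any(!is.finite(c_frac)) || any(c_frac <= 0 | c_frac >= 1)) {
    stop("carbon_pct must lie strictly between 0 and 100", call. = FALSE)
  }
  if (any(!is.finite(n_frac)) || any(n_frac <= 0 | n_frac >= c_frac)) {
    stop("nitrogen_pct must be positive and smaller than carbon_pct",
         call. = FALSE)
  }
  if ("dbh_cm" %in% names(samples)) {
    dbh <- samples$dbh_cm[!is.na(samples$dbh_cm)]
    if (any(dbh < 5)) {
      stop("sampled trees must have DBH >= 5 cm", call. = FALSE)
    }
  }
  invisible(samples)
}

# case-insensitive, whitespace-collapsed species key; open nomenclature
# ("Ficus sp") is matched literally after the same normalisation
canonical_species <- function(x) {
  tolower(gsub("\\s+", " ", trimws(as.character(x))))
}

#' Build a species-traits table with overall-mean fallback fractions
#'
#' Wraps a per-species summary (as returned by [summarize_species()] or read
#' from a published table) together with the overall mean C and N fractions
#' used for species not in the table. The overall mean is by default the
#' unweighted arithmetic mean of the per-species means; `weighting =
#' "samples"` weights each species by its number of samples instead.
#'
#' @param summary Data frame with at least `species`, `c_mean`, `n_mean`
#'   (percent of dry matter) and, for sample weighting, `n_samples`.
#' @param weighting `"species"` (unweighted mean of species means, the
#'   default) or `"samples"` (sample-size weighted).
#' @return An object of class `traits_table`: a list with `species`
#'   (tibble), `overall_carbon` and `overall_nitrogen` (proportions of dry
#'   matter, 0–1) and `weighting`.
#' @seealso [fraction_for_species()], [overall_mean_fraction()]
#' @export
#' @examples
#' tab <- read_traits_summary_csv(savstocks_example("stem_wood_traits.csv"))
#' traits <- traits_table(tab)
#' glance(traits)
traits_table <- function(summary, weighting = c("species", "samples")) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(summary))
  if (nrow(summary) == 0L) {
    stop("traits summary is empty", call. = FALSE)
  }
  req <- c("species", "c_mean", "n_mean")
  missing_cols <- setdiff(req, names(summary))
  if (length(missing_cols)) {
    stop("traits summary missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keys <- canonical_species(summary$species)
  if (anyDuplicated(keys)) {
    stop("duplicate species in traits summary", call. = FALSE)
  }
  if (weighting == "samples" && !"n_samples" %in% names(summary)) {
    stop("weighting = 'samples' needs an n_samples column", call. = FALSE)
  }
  w <- if (weighting == "samples") summary$n_samples else rep(1, nrow(summary))
  structure(
    list(
      species = tibble::as_tibble(summary),
      overall_carbon = pct_to_frac(stats::weighted.mean(summary$c_mean, w)),
      overall_nitrogen = pct_to_frac(stats::weighted.mean(summary$n_mean, w)),
      weighting = weighting
    ),
    class = "traits_table"
  )
}

#' @export
print.traits_table <- function(x, ...) {
  cat("<traits_table> ", nrow(x$species), " species (",
      x$weighting, "-weighted overall means)\n", sep = "")
  cat(sprintf("  overall carbon fraction:   %.5f (%.2f%% dm)\n",
              x$overall_carbon, frac_to_pct(x$overall_carbon)))
  cat(sprintf("  overall nitrogen fraction: %.5f (%.3f%% dm)\n",
              x$overall_nitrogen, frac_to_pct(x$overall_nitrogen)))
  invisible(x)
}

#' @method tidy traits_table
#' @export
tidy.traits_table <- function(x, ...) {
  x$species
}

#' @method glance traits_table
#' @export
glance.traits_table <- function(x, ...) {
  tibble::tibble(
    n_species = nrow(x$species),
    n_samples = if ("n_samples" %in% names(x$species))
      sum(x$species$n_samples) else NA_integer_,
    overall_carbon = x$overall_carbon,
    overall_nitrogen = x$overall_nitrogen,
    weighting = x$weighting
  )
}

#' Overall mean C or N fraction of a traits table
#'
#' @param table A [traits_table()].
#' @param element `"C"` or `"N"`.
#' @return The overall mean fraction of dry matter (proportion, 0–1).
#' @export
overall_mean_fraction <- function(table, element = c("C", "N")) {
  element <- match.arg(element)
  stopifnot(inherits(table, "traits_table"))
  if (element == "C") table$overall_carbon else table$overall_nitrogen
}

#' Resolve the C or N fraction to apply to a tree species
#'
#' Species present in the table get their species-specific mean fraction;
#' any other species falls back to the overall mean. Matching is
#' case-insensitive and whitespace-collapsed. Vectorised over `species`.
#'
#' @inheritParams overall_mean_fraction
#' @param species Character vector of species names.
#' @return A tibble with columns `species`, `element`, `fraction`
#'   (proportion of dry matter) and `provenance`
#'   (`"species-specific"` or `"fallback"`).
#' @export
#' @examples
#' traits <- traits_table(
#'   read_traits_summary_csv(savstocks_example("stem_wood_traits.csv")))
#' fraction_for_species(traits, c("Pterocarpus erinaceus", "Unknown sp."))
fraction_for_species <- function(table, species, element = c("C", "N")) {
  element <- match.arg(element)
  stopifnot(inherits(table, "traits_table"))
  keys <- canonical_species(table$species$species)
  means <- pct_to_frac(
    if (element == "C") table$species$c_mean else table$species$n_mean)
  idx <- match(canonical_species(species), keys)
  fallback <- overall_mean_fraction(table, element)
  tibble::tibble(
    species = as.character(species),
    element = element,
    fraction = ifelse(is.na(idx), fallback, means[idx]),
    provenance = ifelse(is.na(idx), "fallback", "species-specific")
  )
}
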