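# Categorical class maps and per-class stock surfaces. With no raster
# stack required downstream, a map is a plain integer matrix plus grid
# metadata, serialised as ESRI ASCII grid (a line-oriented text format
# every desktop GIS reads).

new_class_map <- function(values, classes, cellsize, xll = 0, yll = 0) {
  stopifnot(is.matrix(values))
  structure(
    list(values = values, classes = as.character(classes),
         cellsize = cellsize, xll = xll, yll = yll),
    class = "class_map"
  )
}

#' @export
print.class_map <- function(x, ...) {
  cat("<class_map> ", nrow(x$values), " x ", ncol(x$values),
      " cells of ", x$cellsize, " m (",
      sum(!is.na(x$values)), " classified)\n", sep = "")
  tab <- class_map_areas(x)
  print(tab)
  invisible(x)
}

#' Per-class cell counts and areas of a class map
#'
#' @param map A `class_map`.
#' @return Tibble with `lulc`, `n_cells`, `area_ha`.
#' @export
class_map_areas <- function(map) {
  stopifnot(inherits(map, "class_map"))
  cell_ha <- map$cellsize^2 / 1e4
  counts <- tabulate(map$values[!is.na(map$values)],
                     nbins = length(map$classes))
  tibble::tibble(lulc = map$classes, n_cells = counts,
                 area_ha = counts * cell_ha)
}

#' Generate a categorical LULC class map matching an area table
#'
#' Builds a seeded synthetic class raster whose per-class areas match the
#' area table to within one cell per class. Cell counts come from
#' rounding `area / cell area`; classes are laid out as contiguous runs
#' along a boustrophedon (snake) scan of the grid, which keeps every
#' class a single connected blob, in a seed-dependent order. Cells beyond
#' the classified total are no-data (the basin also contains water,
#' roads and bare land).
#'
#' @param areas Area table with `lulc` and `area_ha`.
#' @param resolution Cell size in metres (default 30, a Landsat-like
#'   grid).
#' @param seed Integer seed controlling the class layout order.
#' @return A `class_map` object.
#' @export
#' @examples
#' m <- generate_class_map(generate_area_table(), resolution = 120,
#'                         seed = 1)
#' class_map_areas(m)
generate_class_map <- function(areas, resolution = 30, seed = 1) {
  stopifnot(is.data.frame(areas),
            all(c("lulc", "area_ha") %in% names(areas)))
  if (resolution <= 0) stop("resolution must be positive", call. = FALSE)
  cell_ha <- resolution^2 / 1e4
  n_cells <- round(areas$area_ha / cell_ha)
  if (any(n_cells == 0L)) {
    stop("grid too coarse: class(es) ",
         paste(areas$lulc[n_cells == 0L], collapse = ", "),
         " would get no cells", call. = FALSE)
  }
  total <- sum(n_cells)
  n_col <- ceiling(sqrt(total))
  n_row <- ceiling(total / n_col)
  withr::with_seed(as.integer(seed), {
    ord <- sample.int(nrow(areas))
    codes <- rep(ord, n_cells[ord])
  })
  vals <- rep(NA_integer_, n_row * n_col)
  vals[seq_len(total)] <- codes
  m <- matrix(vals, nrow = n_row, ncol = n_col, byrow = TRUE)
  # snake scan: reverse every even row so runs stay 4-connected
  if (n_row >= 2) {
    even <- seq(2, n_row, by = 2)
    m[even, ] <- m[even, n_col:1, drop = FALSE]
  }
  new_class_map(m, areas$lulc, resolution)
}

#' Render a continuous stock-density surface from a class map
#'
#' Each cell takes the mean stock density (Mg/ha) of its LULC class, the
#' legend semantics of class-constant stock maps; no-data cells stay
#' no-data and the grid georeferencing is carried over.
#'
#' @param map A `class_map`.
#' @param estimates A `stock_estimates` tibble with `lulc` and
#'   `mean_density` for a single element (filter before calling if it
#'   holds both C and N).
#' @return A `stock_map`: like `class_map` but with numeric density
#'   values and a `densities` lookup.
#' @export
write_stock_map_values <- function(map, estimates) {
  stopifnot(inherits(map, "class_map"), is.data.frame(estimates))
  if (length(unique(estimates$element)) > 1L) {
    stop("estimates mix elements; filter to C or N first", call. = FALSE)
  }
  lookup <- setNames(estimates$mean_density, estimates$lulc)
  missing_cls <- setdiff(map$classes, names(lookup))
  if (length(missing_cls)) {
    stop("no stock estimate for class(es): ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  }
  dens <- unname(lookup[map$classes])
  vals <- matrix(dens[map$values], nrow = nrow(map$values))
  structure(
    list(values = vals, classes = map$classes, densities = dens,
         cellsize = map$cellsize, xll = map$xll, yll = map$yll),
    class = "stock_map"
  )
}

#' @export
print.stock_map <- function(x, ...) {
  cat("<stock_map> ", nrow(x$values), " x ", ncol(x$values),
      " cells of ", x$cellsize, " m; total stock ",
      sprintf("%.2f", stock_map_total(x)), " Mg\n", sep = "")
  invisible(x)
}

#' Cell-area-weighted total stock of a stock map
#'
#' @param map A `stock_map` from [write_stock_map_values()].
#' @return Total stock in Mg (sum of cell density times cell area).
#' @export
stock_map_total <- function(map) {
  stopifnot(inherits(map, "stock_map"))
  sum(map$values, na.rm = TRUE) * map$cellsize^2 / 1e4
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text raster exchange format: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by one line of
#' cell values per row, north row first.
#'
#' @param map A `class_map` or `stock_map`.
#' @param path Output/input file path.
#' @return `write_ascii_grid()` returns `path` invisibly;
#'   `read_ascii_grid()` returns a list with `values` (matrix),
#'   `cellsize`, `xll`, `yll`.
#' @export
write_ascii_grid <- function(map, path) {
  vals <- map$values
  nodata <- -9999
  out <- vals
  out[is.na(out)] <- nodata
  header <- c(
    paste("ncols", ncol(vals)), paste("nrows", nrow(vals)),
    paste("xllcorner", map$xll), paste("yllcorner", map$yll),
    paste("cellsize", map$cellsize), paste("NODATA_value", nodata))
  body <- apply(out, 1, paste, collapse = " ")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, character(1), 1))
  vals <- as.numeric(vapply(hdr, `[`, character(1), 2))
  h <- setNames(vals, keys)
  m <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  m[m == h[["nodata_value"]]] <- NA
  stopifnot(nrow(m) == h[["nrows"]], ncol(m) == h[["ncols"]])
  list(values = m, cellsize = h[["cellsize"]],
       xll = h[["xllcorner"]], yll = h[["yllcorner"]])
}
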