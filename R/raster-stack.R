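#' Environmental raster stacks
#'
#' An `eco_stack` holds a set of gridded environmental variables sharing one
#' regular latitude/longitude grid. Each layer is a numeric matrix whose rows
#' run north to south (row 1 is the northernmost row, as in an ESRI ASCII
#' grid) and whose columns run west to east. `NA` cells are nodata ("sea").
#' Every layer is tagged with one ecogeographical component: `bioclimatic`,
#' `edaphic` or `geophysic`.
#'
#' @param layers Named list of numeric matrices, all with identical
#'   dimensions and identical `NA` pattern.
#' @param component Named character vector mapping each layer name to
#'   `"bioclimatic"`, `"edaphic"` or `"geophysic"`.
#' @param xmin,ymin Western/southern edge of the grid (decimal degrees,
#'   WGS84).
#' @param cell_size Cell size in decimal degrees (default 1/120, i.e. 30
#'   arc-seconds).
#' @return An object of class `eco_stack`.
#' @export
eco_stack <- function(layers, component, xmin, ymin, cell_size = 1 / 120) {
  stopifnot(is.list(layers), length(layers) >= 1, !is.null(names(layers)))
  dims <- vapply(layers, dim, integer(2))
  if (!all(dims == dims[, 1])) stop("all layers must share one grid", call. = FALSE)
  component <- component[names(layers)]
  if (anyNA(component)) stop("every layer needs a component tag", call. = FALSE)
  bad <- setdiff(unique(component), c("bioclimatic", "edaphic", "geophysic"))
  if (length(bad)) stop("unknown component tag: ", paste(bad, collapse = ", "), call. = FALSE)
  structure(
    list(
      layers = layers, component = component,
      xmin = xmin, ymin = ymin, cell_size = cell_size,
      nrow = unname(dims[1, 1]), ncol = unname(dims[2, 1])
    ),
    class = "eco_stack"
  )
}

#' @export
print.eco_stack <- function(x, ...) {
  cat("<eco_stack> ", x$nrow, "x", x$ncol, " cells @ ", signif(x$cell_size, 4),
    " deg, ", length(x$layers), " layers\n",
    sep = ""
  )
  tab <- table(x$component)
  cat("  components:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat(
    "  extent: lon [", x$xmin, ", ", x$xmin + x$ncol * x$cell_size,
    "], lat [", x$ymin, ", ", x$ymin + x$nrow * x$cell_size, "]\n",
    sep = ""
  )
  invisible(x)
}

#' Locate the grid cell containing a point
#'
#' Containing-cell lookup on the regular lat/lon grid. Cells are half-open
#' intervals `[west, east) x [south, north)` measured from the grid origin,
#' so a point on the shared edge of two cells belongs to the cell to its
#' east/north. Points outside the grid get `NA` indices.
#'
#' @param stack An [eco_stack()].
#' @param lon,lat Numeric vectors of coordinates (decimal degrees).
#' @return A tibble with columns `row`, `col` (matrix indices; `NA` when
#'   outside the extent).
#' @export
cell_index <- function(stack, lon, lat) {
  col <- floor((lon - stack$xmin) / stack$cell_size) + 1
  # row 1 is the top (north); half-open in latitude means the south edge of
  # a cell belongs to it, hence the asymmetric treatment of the top edge
  row_from_south <- floor((lat - stack$ymin) / stack$cell_size) + 1
  row <- stack$nrow - row_from_south + 1
  outside <- col < 1 | col > stack$ncol | row < 1 | row > stack$nrow
  col[outside] <- NA_integer_
  row[outside] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

# centers of all cells, as vectors aligned with as.vector(matrix)
cell_centers <- function(stack) {
  cs <- stack$cell_size
  lon <- stack$xmin + (seq_len(stack$ncol) - 0.5) * cs
  lat_top_down <- stack$ymin + (stack$nrow - seq_len(stack$nrow) + 0.5) * cs
  list(
    lon = rep(lon, each = stack$nrow),
    lat = rep(lat_top_down, times = stack$ncol)
  )
}

# logical vector over cells (column-major) that are land on every layer
land_mask <- function(stack) {
  ok <- !is.na(as.vector(stack$layers[[1]]))
  for (m in stack$layers[-1]) ok <- ok & !is.na(as.vector(m))
  ok
}

#' Convert a raster stack to a long tibble
#'
#' One row per land cell with cell-centre coordinates and one column per
#' layer; useful for plotting and audits.
#'
#' @param x An [eco_stack()].
#' @param ... Unused.
#' @return A tibble with `row`, `col`, `lon`, `lat` and one column per layer.
#' @method as_tibble eco_stack
#' @export
as_tibble.eco_stack <- function(x, ...) {
  cc <- cell_centers(x)
  idx <- which(land_mask(x))
  vals <- purrr::map(x$layers, ~ as.vector(.x)[idx])
  tibble::tibble(
    row = ((idx - 1L) %% x$nrow) + 1L,
    col = ((idx - 1L) %/% x$nrow) + 1L,
    lon = cc$lon[idx], lat = cc$lat[idx],
    !!!vals
  )
}

#' Synthetic latitude/longitude layers for a stack's grid
#'
#' Returns the stack extended with `LATITUDE` and `LONGITUDE` layers (cell
#' centre coordinates, tagged geophysic), masked to the stack's land cells.
#' These are the two positional variables appended to the geophysic
#' component so that ELC categories come out spatially aggregated.
#'
#' @param stack An [eco_stack()].
#' @return An [eco_stack()] with two extra geophysic layers.
#' @export
add_latlon_layers <- function(stack) {
  cc <- cell_centers(stack)
  sea <- !land_mask(stack)
  lat_m <- matrix(cc$lat, nrow = stack$nrow)
  lon_m <- matrix(cc$lon, nrow = stack$nrow)
  lat_m[matrix(sea, nrow = stack$nrow)] <- NA_real_
  lon_m[matrix(sea, nrow = stack$nrow)] <- NA_real_
  layers <- c(stack$layers, list(LATITUDE = lat_m, LONGITUDE = lon_m))
  comp <- c(stack$component, LATITUDE = "geophysic", LONGITUDE = "geophysic")
  eco_stack(layers, comp, stack$xmin, stack$ymin, stack$cell_size)
}
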