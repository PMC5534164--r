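#' Read and write ESRI ASCII grids
#'
#' Plain-text single-band raster I/O in the ESRI ASCII grid format
#' (`ncols`/`nrows`/`xllcorner`/`yllcorner`/`cellsize`/`NODATA_value`
#' header followed by rows from north to south). Values are written with 17
#' significant digits so a write/read cycle reproduces doubles exactly.
#'
#' @param m Numeric matrix, rows north to south; `NA` = nodata.
#' @param path File path.
#' @param xmin,ymin Western/southern grid edge (decimal degrees).
#' @param cell_size Cell size in decimal degrees.
#' @param nodata Nodata sentinel written to file.
#' @return `write_raster_ascii()` returns `path` invisibly;
#'   `read_raster_ascii()` returns a list with `matrix`, `xmin`, `ymin`,
#'   `cell_size`.
#' @export
write_raster_ascii <- function(m, path, xmin, ymin, cell_size, nodata = -9999) {
  stopifnot(is.matrix(m))
  hdr <- c(
    paste("ncols", ncol(m)),
    paste("nrows", nrow(m)),
    paste("xllcorner", formatC(xmin, digits = 17, format = "g")),
    paste("yllcorner", formatC(ymin, digits = 17, format = "g")),
    paste("cellsize", formatC(cell_size, digits = 17, format = "g")),
    paste("NODATA_value", nodata)
  )
  body <- apply(m, 1, function(r) {
    r[is.na(r)] <- nodata
    paste(formatC(r, digits = 17, format = "g"), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_raster_ascii
#' @export
read_raster_ascii <- function(path) {
  if (!file.exists(path)) stop("no such raster file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[startsWith(tolower(hdr), key)]
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  ncols <- val("ncols")
  nrows <- val("nrows")
  nodata <- val("nodata_value")
  body <- strsplit(trimws(lines[-(1:6)]), "\\s+")
  m <- matrix(as.numeric(unlist(body)), nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  list(
    matrix = m, xmin = val("xllcorner"), ymin = val("yllcorner"),
    cell_size = val("cellsize")
  )
}

#' Write a synthetic fixture bundle to disk
#'
#' Writes every layer of a raster stack as an ESRI ASCII grid, a layer
#' manifest (`layers.csv`: layer, component, file), the occurrence table as
#' CSV, and — when ground truth is supplied — the true category raster and
#' the per-component zone-label rasters as additional grids. The bundle
#' round-trips losslessly through [read_fixture_bundle()].
#'
#' @param stack An [eco_stack()].
#' @param occurrences Occurrence tibble (any columns; written as-is).
#' @param path Directory to create/fill.
#' @param truth Optional `ground_truth` object.
#' @return `path`, invisibly.
#' @export
write_fixture_bundle <- function(stack, occurrences, path, truth = NULL) {
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(path, 2) != 0) {
    stop("cannot write fixture bundle to ", path, call. = FALSE)
  }
  files <- sprintf("layer_%03d.asc", seq_along(stack$layers))
  for (i in seq_along(stack$layers)) {
    write_raster_ascii(
      stack$layers[[i]], file.path(path, files[i]),
      stack$xmin, stack$ymin, stack$cell_size
    )
  }
  readr::write_csv(
    tibble::tibble(
      layer = names(stack$layers),
      component = unname(stack$component[names(stack$layers)]),
      file = files
    ),
    file.path(path, "layers.csv")
  )
  readr::write_csv(occurrences, file.path(path, "occurrences.csv"), na = "")
  if (!is.null(truth)) {
    write_raster_ascii(
      truth$category, file.path(path, "true_category.asc"),
      truth$geom$xmin, truth$geom$ymin, truth$geom$cell_size
    )
  }
  invisible(path)
}

#' Read a fixture bundle written by [write_fixture_bundle()]
#'
#' @param path Bundle directory.
#' @return List with `stack` (an [eco_stack()]), `occurrences` (tibble) and
#'   `true_category` (integer matrix, or `NULL` when absent).
#' @export
read_fixture_bundle <- function(path) {
  man <- readr::read_csv(file.path(path, "layers.csv"),
    col_types = readr::cols(.default = readr::col_character())
  )
  rasters <- purrr::map(man$file, ~ read_raster_ascii(file.path(path, .x)))
  layers <- purrr::map(rasters, "matrix")
  names(layers) <- man$layer
  g <- rasters[[1]]
  stack <- eco_stack(
    layers, stats::setNames(man$component, man$layer),
    g$xmin, g$ymin, g$cell_size
  )
  occ <- readr::read_csv(file.path(path, "occurrences.csv"),
    col_types = readr::cols(.default = readr::col_character()),
    na = character()
  )
  # restore the types sample_occurrences() emits; locality keeps "" as-is
  if ("TRUE_CATEGORY" %in% names(occ)) occ$TRUE_CATEGORY <- as.integer(occ$TRUE_CATEGORY)
  if ("DEGRADED" %in% names(occ)) occ$DEGRADED <- as.logical(occ$DEGRADED)
  for (col in intersect(c("DUPLICATE_OF", "UTM_RESOLUTION_M"), names(occ))) {
    occ[[col]][occ[[col]] == ""] <- NA_character_
  }
  tc_path <- file.path(path, "true_category.asc")
  true_category <- NULL
  if (file.exists(tc_path)) {
    tc <- read_raster_ascii(tc_path)
    true_category <- matrix(as.integer(tc$matrix), nrow = nrow(tc$matrix))
  }
  list(stack = stack, occurrences = occ, true_category = true_category)
}
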