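#' Specify a synthetic ecogeographical landscape
#'
#' Describes a synthetic territory used to exercise the whole gap-analysis
#' pipeline with known ground truth. The territory is a regular lat/lon grid
#' with a nodata "sea" margin; within the land area each ecogeographical
#' component (bioclimatic, edaphic, geophysic) is partitioned into
#' `true_k` contiguous Voronoi zones around random seed points, and every
#' variable of a component takes a zone-specific mean plus independent
#' Gaussian cell noise. Designated layers `annual_precipitation` (mm/yr),
#' `annual_mean_temperature` (deg C) and `topsoil_salinity` (dS/m) are
#' produced on realistic scales so the predictive-characterization stage has
#' meaningful inputs.
#'
#' @param extent Numeric `c(xmin, xmax, ymin, ymax)` in decimal degrees.
#' @param cell_size Cell size in decimal degrees (default 1/120 = 30
#'   arc-seconds).
#' @param n_vars Named integer vector: number of variables per component,
#'   e.g. `c(bioclimatic = 5, edaphic = 4, geophysic = 3)`.
#' @param true_k Named integer vector: true number of zones per component
#'   (each between 1 and 8).
#' @param noise_sd Standard deviation of the per-cell Gaussian noise added
#'   on top of zone means, on the standardized scale on which zone means are
#'   separated by at least `2 * zone_scale / (true_k - 1)`.
#' @param zone_scale Scale of the zone mean separation on the standardized
#'   scale (zone mean entries have root-mean-square `zone_scale`).
#' @param n_informative Named integer vector: how many variables per
#'   component carry the zone structure (defaults to all). The remaining
#'   variables are pure noise with zone mean 0, useful for importance-
#'   ranking tests. Within a component the first `true_k - 1` informative
#'   variables have mutually uncorrelated zone profiles; any further ones
#'   take random directions and may correlate.
#' @param corr_pairs List of `list(partner, name, r)` entries: each adds a
#'   redundant layer `name` in the partner's component, constructed to have
#'   Pearson correlation `r` with layer `partner`.
#' @param sea_margin Width of the nodata margin, in cells (>= 1).
#' @param seed Integer seed; identical specs with identical seeds generate
#'   bit-identical landscapes.
#' @return An object of class `landscape_spec`.
#' @export
landscape_spec <- function(extent = c(-4, -3, 40, 41),
                           cell_size = 1 / 120,
                           n_vars = c(bioclimatic = 6, edaphic = 5, geophysic = 2),
                           true_k = c(bioclimatic = 3, edaphic = 3, geophysic = 3),
                           noise_sd = 0.25,
                           zone_scale = 3,
                           n_informative = NULL,
                           corr_pairs = list(),
                           sea_margin = 2,
                           seed = 1L) {
  if (is.null(n_informative)) n_informative <- n_vars
  spec <- structure(
    list(
      extent = extent, cell_size = cell_size, n_vars = n_vars,
      true_k = true_k, noise_sd = noise_sd, zone_scale = zone_scale,
      n_informative = n_informative,
      corr_pairs = corr_pairs, sea_margin = as.integer(sea_margin),
      seed = as.integer(seed)
    ),
    class = "landscape_spec"
  )
  validate_landscape_spec(spec)
  spec
}

validate_landscape_spec <- function(spec) {
  comps <- c("bioclimatic", "edaphic", "geophysic")
  if (length(spec$extent) != 4 ||
    spec$extent[2] <= spec$extent[1] || spec$extent[4] <= spec$extent[3]) {
    stop("extent must be c(xmin, xmax, ymin, ymax) with positive spans", call. = FALSE)
  }
  if (!all(comps %in% names(spec$n_vars)) || !all(comps %in% names(spec$true_k))) {
    stop("n_vars and true_k need entries for all three components", call. = FALSE)
  }
  if (any(spec$true_k < 1) || any(spec$true_k > 8)) {
    stop("true_k must be between 1 and 8 per component", call. = FALSE)
  }
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!all(names(spec$n_vars) %in% names(spec$n_informative)) ||
    any(spec$n_informative[names(spec$n_vars)] > spec$n_vars)) {
    stop("n_informative must be named like n_vars and <= n_vars", call. = FALSE)
  }
  if (spec$sea_margin < 1) stop("sea_margin must be >= 1 cell", call. = FALSE)
  for (cp in spec$corr_pairs) {
    if (!all(c("partner", "name", "r") %in% names(cp)) || abs(cp$r) > 1) {
      stop("each corr_pair needs partner, name and |r| <= 1", call. = FALSE)
    }
  }
  ncol <- floor((spec$extent[2] - spec$extent[1]) / spec$cell_size + 1e-9)
  nrow <- floor((spec$extent[4] - spec$extent[3]) / spec$cell_size + 1e-9)
  if (ncol - 2 * spec$sea_margin < 2 || nrow - 2 * spec$sea_margin < 2) {
    stop("degenerate extent: no land cells inside the sea margin", call. = FALSE)
  }
  invisible(spec)
}

# Zone mean levels per variable. Informative variables take directions in
# the (k-1)-dimensional contrast space of the k zones, orthonormalized
# under the realized zone weights (cell shares), so that over the
# landscape the first k-1 informative variables of a component have
# (near-)zero mutual correlation and correlation pruning cannot wipe out a
# component. Later informative variables take random unit directions and
# may correlate, as real environmental layers do. Non-informative
# variables have zone mean 0 everywhere: pure noise.
zone_mean_matrix <- function(k, n_vars, n_info, zone_scale, weights = NULL) {
  mu <- matrix(0, nrow = k, ncol = n_vars)
  if (k == 1 || n_info == 0) {
    return(mu)
  }
  w <- weights %||% rep(1 / k, k)
  w <- w / sum(w)
  wdot <- function(a, b) sum(w * a * b)
  # weighted Gram-Schmidt on random start vectors, all weighted-mean-zero
  basis <- matrix(0, k, k - 1)
  got <- 0L
  while (got < k - 1) {
    cand <- stats::rnorm(k)
    cand <- cand - sum(w * cand)
    for (j in seq_len(got)) cand <- cand - wdot(cand, basis[, j]) * basis[, j]
    nrm <- sqrt(wdot(cand, cand))
    if (nrm > 1e-8) {
      got <- got + 1L
      basis[, got] <- cand / nrm
    }
  }
  for (v in seq_len(min(n_info, n_vars))) {
    d <- if (v <= k - 1) {
      # small mixing off the exact orthonormal frame: a perfectly symmetric
      # zone simplex sits on the elbow rule's 50% boundary, where the chosen
      # k is decided by floating-point noise
      cf <- stats::rnorm(k - 1, sd = 0.08)
      cand <- basis[, v] + as.vector(basis %*% cf)
      cand / sqrt(wdot(cand, cand))
    } else {
      cf <- stats::rnorm(k - 1)
      as.vector(basis %*% (cf / sqrt(sum(cf^2))))
    }
    mu[, v] <- d * zone_scale
  }
  mu
}

# realistic affine scales for the designated predictive-characterization
# layers; everything else stays on the standardized scale
designated_transforms <- list(
  annual_precipitation = function(z) pmax(0, 600 + 80 * z),
  annual_mean_temperature = function(z) 14 + 1.5 * z,
  topsoil_salinity = function(z) pmax(0, 3 + 0.45 * z)
)

#' Generate a synthetic raster stack with ground truth
#'
#' Builds one raster layer per requested variable. Zone structure is a set
#' of Voronoi patches per component around random seed points; every cell of
#' a zone shares the zone's mean vector, plus i.i.d. Gaussian noise. Layers
#' named in `corr_pairs` are linear transforms (plus noise) of their partner
#' layer, planted as known-redundant variables for the correlation-pruning
#' stage. A sea margin of nodata cells surrounds the land area.
#'
#' The first two bioclimatic variables are named `annual_precipitation` and
#' `annual_mean_temperature` and the first edaphic variable
#' `topsoil_salinity` (when the component has that many variables), rescaled
#' to realistic units; all remaining variables are named
#' `bio03...`/`eda02...`/`geo01...` and kept standardized.
#'
#' @param spec A [landscape_spec()].
#' @return A list with elements `stack` (an [eco_stack()]) and `truth` (a
#'   `ground_truth` object holding the true category raster, per-component
#'   zone labels, zone mean vectors and the planted-redundant layer names).
#' @examples
#' land <- generate_raster_stack(landscape_spec(
#'   extent = c(0, 0.5, 40, 40.5),
#'   cell_size = 1 / 60, seed = 7
#' ))
#' land$stack
#' @export
generate_raster_stack <- function(spec) {
  validate_landscape_spec(spec)
  set.seed(spec$seed)
  comps <- c("bioclimatic", "edaphic", "geophysic")

  ncol <- floor((spec$extent[2] - spec$extent[1]) / spec$cell_size + 1e-9)
  nrow <- floor((spec$extent[4] - spec$extent[3]) / spec$cell_size + 1e-9)
  m <- spec$sea_margin
  land <- matrix(FALSE, nrow, ncol)
  land[(m + 1):(nrow - m), (m + 1):(ncol - m)] <- TRUE
  land_idx <- which(land) # column-major
  n_land <- length(land_idx)

  geom <- list(
    xmin = spec$extent[1], ymin = spec$extent[3],
    cell_size = spec$cell_size, nrow = nrow, ncol = ncol
  )
  cc <- cell_centers(geom)
  lon <- cc$lon[land_idx]
  lat <- cc$lat[land_idx]

  # Voronoi zones per component: label = nearest of true_k seed cells
  zone_labels <- list()
  for (comp in comps) {
    k <- spec$true_k[[comp]]
    seeds <- sample(n_land, k)
    d2 <- outer(lon, lon[seeds], "-")^2 + outer(lat, lat[seeds], "-")^2
    zone_labels[[comp]] <- max.col(-d2, ties.method = "first")
  }

  var_names <- list(
    bioclimatic = sprintf("bio%02d", seq_len(spec$n_vars[["bioclimatic"]])),
    edaphic = sprintf("eda%02d", seq_len(spec$n_vars[["edaphic"]])),
    geophysic = sprintf("geo%02d", seq_len(spec$n_vars[["geophysic"]]))
  )
  if (spec$n_vars[["bioclimatic"]] >= 1) var_names$bioclimatic[1] <- "annual_precipitation"
  if (spec$n_vars[["bioclimatic"]] >= 2) var_names$bioclimatic[2] <- "annual_mean_temperature"
  if (spec$n_vars[["edaphic"]] >= 1) var_names$edaphic[1] <- "topsoil_salinity"

  layers <- list()
  component <- character()
  zone_means <- list()
  for (comp in comps) {
    k <- spec$true_k[[comp]]
    nv <- spec$n_vars[[comp]]
    zw <- tabulate(zone_labels[[comp]], nbins = k)
    mu <- zone_mean_matrix(
      k, nv, spec$n_informative[[comp]], spec$zone_scale,
      weights = zw
    )
    colnames(mu) <- var_names[[comp]]
    for (v in seq_len(nv)) {
      vn <- var_names[[comp]][v]
      z <- mu[zone_labels[[comp]], v]
      if (spec$noise_sd > 0) z <- z + stats::rnorm(n_land, 0, spec$noise_sd)
      tr <- designated_transforms[[vn]]
      if (!is.null(tr)) {
        z <- tr(z)
        mu[, v] <- tr(mu[, v])
      }
      lay <- matrix(NA_real_, nrow, ncol)
      lay[land_idx] <- z
      layers[[vn]] <- lay
      component[vn] <- comp
    }
    zone_means[[comp]] <- mu
  }

  # planted-redundant layers: target-r linear combination of the partner
  redundant <- character()
  for (cp in spec$corr_pairs) {
    if (!cp$partner %in% names(layers)) {
      stop("corr_pair partner not generated: ", cp$partner, call. = FALSE)
    }
    x <- layers[[cp$partner]][land_idx]
    xs <- as.vector(scale(x))
    e <- stats::rnorm(n_land)
    z <- cp$r * xs + sqrt(1 - cp$r^2) * as.vector(scale(e))
    lay <- matrix(NA_real_, nrow, ncol)
    lay[land_idx] <- z
    layers[[cp$name]] <- lay
    component[cp$name] <- component[[cp$partner]]
    redundant <- c(redundant, cp$name)
  }

  stack <- eco_stack(layers, component, spec$extent[1], spec$extent[3], spec$cell_size)

  # true ELC categories = consecutive ids of observed (bio, eda, geo) triples,
  # lexicographic, matching combine_components()
  triples <- paste(
    zone_labels$bioclimatic, zone_labels$edaphic, zone_labels$geophysic,
    sep = "-"
  )
  key <- order(
    zone_labels$bioclimatic, zone_labels$edaphic, zone_labels$geophysic
  )
  cat_ids <- match(triples, unique(triples[key]))
  cat_m <- matrix(NA_integer_, nrow, ncol)
  cat_m[land_idx] <- cat_ids

  label_rasters <- purrr::map(zone_labels, function(lbl) {
    lm <- matrix(NA_integer_, nrow, ncol)
    lm[land_idx] <- lbl
    lm
  })

  truth <- structure(
    list(
      category = cat_m,
      component_labels = label_rasters,
      zone_means = zone_means,
      redundant_vars = redundant,
      geom = geom
    ),
    class = "ground_truth"
  )
  list(stack = stack, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(
    "<ground_truth> ", length(unique(stats::na.omit(as.vector(x$category)))),
    " true categories; zones per component: ",
    paste(vapply(x$component_labels, function(m) max(m, na.rm = TRUE), 1),
      collapse = "/"
    ), "\n",
    sep = ""
  )
  invisible(x)
}

# uniform jitter inside a cell, kept off the cell edges so that printing at
# 6 decimals cannot move a point into a neighbouring cell
jitter_in_cell <- function(truth, row, col) {
  g <- truth$geom
  u <- stats::runif(length(row), 0.05, 0.95)
  v <- stats::runif(length(row), 0.05, 0.95)
  lon <- g$xmin + (col - 1 + u) * g$cell_size
  # row r (from the top) spans [ymin + (nrow - r) * cs, ymin + (nrow - r + 1) * cs)
  lat <- g$ymin + (g$nrow - row + v) * g$cell_size
  list(lon = lon, lat = lat)
}

#' Sample synthetic occurrence records
#'
#' Draws accession and external-source records from the land cells of a
#' synthetic landscape. Accessions never fall in `withheld_categories`, so
#' those categories are guaranteed ecogeographical gaps; when external
#' records are requested, at least one is planted in every withheld category
#' that has land. A fraction of records receive an injected spatial
#' duplicate (a twin less than 1 km away) and a fraction of the external
#' records are degraded (coordinates truncated to one decimal and locality
#' text removed) so the precision filter has work to do.
#'
#' @param truth A `ground_truth` object from [generate_raster_stack()].
#' @param n_accessions,n_external Number of base records per source class.
#' @param withheld_categories Integer vector of true category ids kept free
#'   of accessions.
#' @param dup_fraction Fraction of base records (per class) that get a twin;
#'   the twin count is `round_half_up(fraction * n)`.
#' @param degrade_fraction Fraction of external records degraded to
#'   low-precision coordinates without locality text.
#' @param accession_cluster_sd Spatial bias of the accessions: when not
#'   `NULL`, accessions are drawn with weights from a Gaussian kernel of
#'   this standard deviation (as a fraction of the larger extent span)
#'   around a random centre, emulating the concentration of collecting
#'   missions in a few regions; externals stay uniform over the species'
#'   range.
#' @param species Species name stored on every record.
#' @param seed Integer seed.
#' @return A tibble in the MCPD-style occurrence CSV dialect (see
#'   [parse_occurrences()]) with extra ground-truth columns `TRUE_CATEGORY`,
#'   `DUPLICATE_OF` and `DEGRADED`.
#' @export
sample_occurrences <- function(truth, n_accessions, n_external,
                               withheld_categories = integer(),
                               dup_fraction = 0, degrade_fraction = 0,
                               accession_cluster_sd = NULL,
                               species = "Synthetica exempli",
                               seed = 1L) {
  set.seed(seed)
  g <- truth$geom
  cat_v <- as.vector(truth$category)
  land_idx <- which(!is.na(cat_v))
  withheld_categories <- as.integer(withheld_categories)
  if (!all(withheld_categories %in% cat_v[land_idx])) {
    stop("withheld_categories must be existing true categories", call. = FALSE)
  }

  acc_pool <- land_idx[!cat_v[land_idx] %in% withheld_categories]
  if (n_accessions > length(acc_pool)) {
    stop("n_accessions exceeds available land cells outside withheld categories",
      call. = FALSE
    )
  }
  if (n_external > length(land_idx)) {
    stop("n_external exceeds available land cells", call. = FALSE)
  }

  if (!is.null(accession_cluster_sd) && n_accessions > 0) {
    cc <- cell_centers(g)
    span <- max(g$ncol, g$nrow) * g$cell_size
    centre <- sample(acc_pool, 1)
    sdd <- accession_cluster_sd * span
    w <- exp(-((cc$lon[acc_pool] - cc$lon[centre])^2 +
      (cc$lat[acc_pool] - cc$lat[centre])^2) / (2 * sdd^2))
    acc_cells <- sample(acc_pool, n_accessions, prob = w)
  } else {
    acc_cells <- sample(acc_pool, n_accessions)
  }
  # guarantee external presence in every withheld category
  forced <- vapply(
    withheld_categories,
    function(ct) sample(land_idx[cat_v[land_idx] == ct], 1), numeric(1)
  )
  n_free <- max(0L, n_external - length(forced))
  ext_cells <- c(forced[seq_len(min(length(forced), n_external))],
    sample(setdiff(land_idx, forced), n_free))

  build <- function(cells, class, prefix) {
    if (!length(cells)) {
      return(empty_occurrence_tibble())
    }
    row <- ((cells - 1L) %% g$nrow) + 1L
    col <- ((cells - 1L) %/% g$nrow) + 1L
    pt <- jitter_in_cell(truth, row, col)
    n <- length(cells)
    adm_band <- pmin(4L, pmax(1L, ceiling(4 * (pt$lon - g$xmin) /
      (g$ncol * g$cell_size))))
    tibble::tibble(
      RECORD_ID = sprintf("%s%04d", prefix, seq_len(n)),
      SPECIES = species,
      SOURCE_CLASS = class,
      DECLATITUDE = sprintf("%.6f", pt$lat),
      DECLONGITUDE = sprintf("%.6f", pt$lon),
      COORD_SYSTEM = "DD",
      UTM_RESOLUTION_M = NA_character_,
      LOCALITY = sprintf("synthetic site r%dc%d", row, col),
      COUNTRY = "Synthlandia",
      ADM1 = sprintf("Region%02d", adm_band),
      ADM2 = sprintf("Province%03d", col %/% 8L + 1L),
      ADM3 = sprintf("Municipality%04d", cells %% 997L),
      TRUE_CATEGORY = cat_v[cells],
      DUPLICATE_OF = NA_character_,
      DEGRADED = FALSE
    )
  }

  acc <- build(acc_cells, "accession", "ACC")
  ext <- build(ext_cells, "external", "EXT")

  inject_twins <- function(tbl, prefix) {
    n_dup <- round_half_up(dup_fraction * nrow(tbl))
    if (n_dup < 1) {
      return(tbl)
    }
    src <- tbl[sample(nrow(tbl), n_dup), ]
    lat0 <- as.numeric(src$DECLATITUDE)
    lon0 <- as.numeric(src$DECLONGITUDE)
    d_km <- stats::runif(n_dup, 0.1, 0.9)
    theta <- stats::runif(n_dup, 0, 2 * pi)
    km_per_deg <- 6371.0088 * pi / 180
    lat1 <- lat0 + d_km * cos(theta) / km_per_deg
    lon1 <- lon0 + d_km * sin(theta) / (km_per_deg * cos(lat0 * pi / 180))
    # twin category from its own cell; may differ near zone borders
    idx <- cell_index(g, lon1, lat1)
    cell <- (idx$col - 1L) * g$nrow + idx$row
    twin_cat <- ifelse(is.na(cell), NA_integer_, cat_v[cell])
    # accession twins may not drift into withheld categories or the sea:
    # collapse those onto their source point
    if (prefix == "ACC") {
      bad <- is.na(twin_cat) | twin_cat %in% withheld_categories
      lat1[bad] <- lat0[bad] + 1e-4
      lon1[bad] <- lon0[bad]
      twin_cat[bad] <- src$TRUE_CATEGORY[bad]
    }
    twins <- src
    twins$RECORD_ID <- sprintf("%sD%03d", prefix, seq_len(n_dup))
    twins$DECLATITUDE <- sprintf("%.6f", lat1)
    twins$DECLONGITUDE <- sprintf("%.6f", lon1)
    twins$TRUE_CATEGORY <- twin_cat
    twins$DUPLICATE_OF <- src$RECORD_ID
    dplyr::bind_rows(tbl, twins)
  }

  acc <- inject_twins(acc, "ACC")
  ext <- inject_twins(ext, "EXT")

  n_deg <- round_half_up(degrade_fraction * nrow(ext))
  if (n_deg >= 1) {
    pick <- sample(nrow(ext), n_deg)
    trunc1 <- function(s) sprintf("%.1f", trunc(as.numeric(s) * 10) / 10)
    ext$DECLATITUDE[pick] <- trunc1(ext$DECLATITUDE[pick])
    ext$DECLONGITUDE[pick] <- trunc1(ext$DECLONGITUDE[pick])
    ext$LOCALITY[pick] <- ""
    ext$DEGRADED[pick] <- TRUE
  }

  dplyr::bind_rows(acc, ext)
}

empty_occurrence_tibble <- function() {
  tibble::tibble(
    RECORD_ID = character(), SPECIES = character(), SOURCE_CLASS = character(),
    DECLATITUDE = character(), DECLONGITUDE = character(),
    COORD_SYSTEM = character(), UTM_RESOLUTION_M = character(),
    LOCALITY = character(), COUNTRY = character(), ADM1 = character(),
    ADM2 = character(), ADM3 = character(),
    TRUE_CATEGORY = integer(), DUPLICATE_OF = character(), DEGRADED = logical()
  )
}
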