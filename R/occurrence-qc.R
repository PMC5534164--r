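#' Parse an occurrence table
#'
#' Reads germplasm accession / external-source occurrence records from the
#' MCPD-style CSV dialect (columns `RECORD_ID`, `SPECIES`, `SOURCE_CLASS`,
#' `DECLATITUDE`, `DECLONGITUDE`, `COORD_SYSTEM`, `UTM_RESOLUTION_M`,
#' `LOCALITY`, `COUNTRY`, `ADM1`, `ADM2`, `ADM3`). Coordinates are kept as
#' text so the number of declared decimals — the basis of the precision
#' filter — is taken from what was written, not from a parsed float.
#' Records whose coordinates are missing or unparseable are flagged
#' `removed_no_coords`, never dropped silently. A Unicode minus sign is
#' accepted as a negative sign.
#'
#' @param x Path to a CSV file, or a data frame already in the dialect.
#' @return A tibble of occurrence records, one row per input row, with
#'   columns `record_id`, `species`, `source_class`, `latitude`,
#'   `longitude`, `lat_text`, `lon_text`, `dec_lat`, `dec_lon`,
#'   `coord_system`, `utm_resolution_m`, `locality`, `country`,
#'   `adm1`–`adm3`, `qc_status` (`"retained"` or `"removed_no_coords"`),
#'   `quality_score` (`NA` until scored) and `elc_category` (0 until
#'   assigned).
#' @export
parse_occurrences <- function(x) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop("no such occurrence file: ", x, call. = FALSE)
    x <- readr::read_csv(x,
      col_types = readr::cols(.default = readr::col_character()),
      na = character()
    )
  }
  x <- tibble::as_tibble(x)
  names(x) <- toupper(names(x))
  mandatory <- c("RECORD_ID", "SPECIES", "SOURCE_CLASS", "DECLATITUDE", "DECLONGITUDE")
  missing_cols <- setdiff(mandatory, names(x))
  if (length(missing_cols)) {
    stop("missing mandatory columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  opt <- function(col, default = "") {
    if (col %in% names(x)) tidyr::replace_na(as.character(x[[col]]), default) else rep(default, nrow(x))
  }

  lat_text <- clean_coord_text(as.character(x$DECLATITUDE))
  lon_text <- clean_coord_text(as.character(x$DECLONGITUDE))
  latitude <- suppressWarnings(as.numeric(lat_text))
  longitude <- suppressWarnings(as.numeric(lon_text))
  bad <- is.na(latitude) | is.na(longitude) |
    latitude < -90 | latitude > 90 | longitude < -180 | longitude > 180
  latitude[bad] <- NA_real_
  longitude[bad] <- NA_real_

  utm_res <- suppressWarnings(as.numeric(opt("UTM_RESOLUTION_M", NA_character_)))

  tibble::tibble(
    record_id = as.character(x$RECORD_ID),
    species = as.character(x$SPECIES),
    source_class = tolower(as.character(x$SOURCE_CLASS)),
    latitude = latitude,
    longitude = longitude,
    lat_text = lat_text,
    lon_text = lon_text,
    dec_lat = decimal_count(lat_text),
    dec_lon = decimal_count(lon_text),
    coord_system = toupper(opt("COORD_SYSTEM", "DD")),
    utm_resolution_m = utm_res,
    locality = opt("LOCALITY"),
    country = opt("COUNTRY"),
    adm1 = opt("ADM1"), adm2 = opt("ADM2"), adm3 = opt("ADM3"),
    qc_status = ifelse(bad, "removed_no_coords", "retained"),
    quality_score = NA_real_,
    elc_category = 0L
  )
}

clean_coord_text <- function(s) {
  s <- gsub("−", "-", trimws(s)) # Unicode minus
  s[s == ""] <- NA_character_
  s
}

#' Count declared decimals in a coordinate string
#'
#' @param s Character vector of coordinate texts.
#' @return Integer vector: digits after the decimal point as written (0 when
#'   no decimal point, `NA` for missing input).
#' @examples
#' decimal_count(c("41.700833", "-0.1", "42", NA))
#' @export
decimal_count <- function(s) {
  out <- rep(NA_integer_, length(s))
  has <- !is.na(s)
  frac <- stringr::str_match(s[has], "^[-+]?[0-9]*\\.([0-9]+)\\s*$")[, 2]
  out[has] <- ifelse(is.na(frac), 0L, nchar(frac))
  out
}

#' Remove low-precision external records
#'
#' Applies the coordinate-precision rule: an external-source record still in
#' play is marked `removed_low_precision` when (a) its coordinates are in
#' decimal degrees with fewer than two declared decimals in *both* latitude
#' and longitude, or (b) it has no locality text, or (c) its coordinates
#' come from a UTM square coarser than 1x1 km. Genebank accessions are never
#' removed by this rule.
#'
#' @param records Parsed occurrence tibble (see [parse_occurrences()]).
#' @param max_utm_res_m Coarsest acceptable UTM resolution, metres.
#' @return `records` with `qc_status` updated.
#' @export
precision_filter <- function(records, max_utm_res_m = 1000) {
  in_play <- records$qc_status == "retained" & records$source_class == "external"
  dd_coarse <- records$coord_system == "DD" &
    records$dec_lat < 2 & records$dec_lon < 2
  no_text <- is.na(records$locality) | trimws(records$locality) == ""
  utm_coarse <- records$coord_system == "UTM" &
    !is.na(records$utm_resolution_m) & records$utm_resolution_m > max_utm_res_m
  drop <- in_play & (dd_coarse | no_text | utm_coarse)
  records$qc_status[drop] <- "removed_low_precision"
  records
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km (the IUGG mean
#' Earth radius). Vectorized over point pairs.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Numeric vector of distances in km.
#' @examples
#' haversine_km(0, 0, 0, 1) # one degree of longitude at the equator
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# n x m distance matrix between two point sets
haversine_cross <- function(lat1, lon1, lat2, lon2) {
  outer(seq_along(lat1), seq_along(lat2), function(i, j) {
    haversine_km(lat1[i], lon1[i], lat2[j], lon2[j])
  })
}

#' Clear intraspecific spatial duplicates
#'
#' Occurrences of the same species and source class less than `threshold_km`
#' apart are treated as one population: a deterministic greedy scan
#' (quality score descending, then record id ascending) retains a record iff
#' it lies at least `threshold_km` from every already-retained record of its
#' group. Records at exactly the threshold are kept — duplicates are
#' strictly *less than* 1 km apart. Removed records get `qc_status
#' = "removed_duplicate"`.
#'
#' @param records Parsed occurrence tibble; only rows with `qc_status ==
#'   "retained"` take part.
#' @param threshold_km Duplicate distance threshold in km.
#' @return `records` with `qc_status` updated.
#' @export
dedup_spatial <- function(records, threshold_km = 1.0) {
  live_idx <- which(records$qc_status == "retained")
  groups <- split(
    live_idx,
    paste(records$species[live_idx], records$source_class[live_idx], sep = "\r")
  )
  for (g in groups) {
    q <- records$quality_score[g]
    q[is.na(q)] <- -Inf
    ord <- g[order(-q, records$record_id[g])]
    kept_lat <- numeric(0)
    kept_lon <- numeric(0)
    for (i in ord) {
      la <- records$latitude[i]
      lo <- records$longitude[i]
      if (length(kept_lat) &&
        any(haversine_km(la, lo, kept_lat, kept_lon) < threshold_km)) {
        records$qc_status[i] <- "removed_duplicate"
      } else {
        kept_lat <- c(kept_lat, la)
        kept_lon <- c(kept_lon, lo)
      }
    }
  }
  records
}

#' Score georeferencing quality
#'
#' A 0-100 composite quality score standing in for a full georeferencing
#' audit. It averages up to three sub-scores in \[0, 1\]:
#'
#' * *coordinate precision*: declared decimal count `d` mapped to
#'   `min(d, 4) / 4` (both axes must reach it: the minimum of the two
#'   counts is used); UTM resolutions map to 1 (<= 100 m), 0.75 (<= 1 km),
#'   0.25 (<= 10 km), 0 (coarser).
#' * *administrative agreement*: the record's point is tested against the
#'   declared administrative units in `admin_reference`, finest declared
#'   level first. Containment at the finest checkable level scores that
#'   level's weight (country 0.25, adm1 0.5, adm2 0.75, adm3 1);
#'   non-containment scores 0. Skipped (with a warning) when no reference is
#'   supplied, in which case the remaining two sub-scores are averaged.
#' * *locality completeness*: half for non-empty locality text, half for at
#'   least one non-empty administrative field.
#'
#' Improving any sub-score never lowers the total.
#'
#' @param records Parsed occurrence tibble.
#' @param admin_reference Optional admin polygon table from
#'   [read_admin_geojson()] (columns `level`, `name`, `ring`).
#' @return `records` with `quality_score` filled in (0-100 scale).
#' @export
score_georeferencing_quality <- function(records, admin_reference = NULL) {
  d <- pmin(records$dec_lat, records$dec_lon)
  s_prec <- ifelse(
    records$coord_system == "UTM",
    utm_precision_score(records$utm_resolution_m),
    pmin(ifelse(is.na(d), 0, d), 4) / 4
  )
  has_locality <- !(is.na(records$locality) | trimws(records$locality) == "")
  has_admin <- trimws(paste0(
    records$country, records$adm1, records$adm2, records$adm3
  )) != ""
  s_loc <- 0.5 * has_locality + 0.5 * has_admin

  if (is.null(admin_reference)) {
    rlang::warn(
      "no admin_reference supplied: admin-agreement sub-score skipped",
      .frequency = "once", .frequency_id = "elcgap_no_admin"
    )
    score <- 100 * (s_prec + s_loc) / 2
  } else {
    s_admin <- admin_agreement_score(records, admin_reference)
    # records with no checkable admin declaration fall back to two sub-scores
    score <- 100 * rowMeans(cbind(s_prec, s_admin, s_loc), na.rm = TRUE)
  }
  records$quality_score <- score
  records
}

utm_precision_score <- function(res_m) {
  dplyr::case_when(
    is.na(res_m) ~ 0,
    res_m <= 100 ~ 1,
    res_m <= 1000 ~ 0.75,
    res_m <= 10000 ~ 0.25,
    .default = 0
  )
}

admin_level_weights <- c(country = 0.25, adm1 = 0.5, adm2 = 0.75, adm3 = 1)

admin_agreement_score <- function(records, admin_reference) {
  vapply(seq_len(nrow(records)), function(i) {
    for (lvl in c("adm3", "adm2", "adm1", "country")) {
      nm <- records[[lvl]][i]
      if (is.na(nm) || trimws(nm) == "") next
      poly <- admin_reference[admin_reference$level == lvl &
        admin_reference$name == nm, ]
      if (!nrow(poly)) next
      inside <- any(vapply(poly$ring, function(rg) {
        sp::point.in.polygon(
          records$longitude[i], records$latitude[i], rg[, 1], rg[, 2]
        ) > 0
      }, logical(1)))
      return(if (inside) unname(admin_level_weights[lvl]) else 0)
    }
    NA_real_ # nothing checkable: neutral, excluded from the mean
  }, numeric(1))
}

#' Read administrative boundaries from GeoJSON
#'
#' Minimal reader for a GeoJSON `FeatureCollection` of (multi)polygons with
#' properties `level` (`country`/`adm1`/`adm2`/`adm3`) and `name`, as used
#' by the admin-agreement quality sub-score.
#'
#' @param path GeoJSON file path.
#' @return A tibble with columns `level`, `name` and `ring` (list of
#'   two-column lon/lat matrices, one row per outer ring).
#' @export
read_admin_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  rows <- purrr::map(gj$features, function(f) {
    geom <- f$geometry
    polys <- if (geom$type == "Polygon") list(geom$coordinates) else geom$coordinates
    rings <- purrr::map(polys, function(p) {
      ring <- p[[1]] # outer ring only
      matrix(unlist(ring), ncol = 2, byrow = TRUE)
    })
    tibble::tibble(
      level = f$properties$level, name = f$properties$name, ring = rings
    )
  })
  dplyr::bind_rows(rows)
}

#' Full occurrence quality-control pipeline
#'
#' Runs the QC stages in order: precision filter (externals only), quality
#' scoring, spatial deduplication at `threshold_km`, and the quality
#' threshold (records scoring strictly above `quality_threshold` pass).
#' The result keeps every input record with its final `qc_status`
#' (`retained`, `removed_no_coords`, `removed_low_precision`,
#' `removed_duplicate`) — the four statuses partition the input — plus a
#' logical `quality_pass` for retained records.
#'
#' @param records Parsed occurrence tibble (see [parse_occurrences()]).
#' @param threshold_km Duplicate distance, km.
#' @param quality_threshold Pass mark on the 0-100 quality score.
#' @param admin_reference Optional admin polygons (see
#'   [score_georeferencing_quality()]).
#' @return `records` with `qc_status`, `quality_score` and `quality_pass`.
#' @export
qc_pipeline <- function(records, threshold_km = 1.0, quality_threshold = 80,
                        admin_reference = NULL) {
  records <- precision_filter(records)
  records <- score_georeferencing_quality(records, admin_reference)
  records <- dedup_spatial(records, threshold_km)
  records$quality_pass <- records$qc_status == "retained" &
    records$quality_score > quality_threshold
  records
}

#' Per-species quality-control report
#'
#' Summarizes a QC'd occurrence table per species and source class in the
#' layout of a genebank curation report: initial georeferenced records,
#' records removed for low accuracy, spatial duplicates removed, and
#' non-duplicated records below and above the quality threshold, each with
#' its percentage of the initial count (round-half-up to integer percent).
#'
#' @param records Output of [qc_pipeline()].
#' @return A tibble with one row per species x source class.
#' @export
qc_report <- function(records) {
  records |>
    dplyr::filter(.data$qc_status != "removed_no_coords") |>
    dplyr::group_by(.data$species, .data$source_class) |>
    dplyr::summarise(
      n_initial = dplyr::n(),
      n_low_precision = sum(.data$qc_status == "removed_low_precision"),
      n_duplicates = sum(.data$qc_status == "removed_duplicate"),
      n_quality_le = sum(.data$qc_status == "retained" & !.data$quality_pass),
      n_quality_gt = sum(.data$qc_status == "retained" & .data$quality_pass),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pct_low_precision = pct_int(.data$n_low_precision, .data$n_initial),
      pct_duplicates = pct_int(.data$n_duplicates, .data$n_initial),
      pct_quality_le = pct_int(.data$n_quality_le, .data$n_initial),
      pct_quality_gt = pct_int(.data$n_quality_gt, .data$n_initial)
    )
}
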