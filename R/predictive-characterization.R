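#' Lang aridity index
#'
#' `AI_L = annual precipitation (mm/yr) / annual mean temperature (deg C)`.
#' Lower values indicate more arid sites. Undefined (NA) where the annual
#' mean temperature is not positive.
#'
#' @param precipitation_mm Annual precipitation, mm/yr.
#' @param temperature_c Annual mean temperature, deg C.
#' @return Numeric vector of index values (`NA` where `temperature_c <= 0`).
#' @examples
#' lang_aridity_index(580, 20) # 29
#' @export
lang_aridity_index <- function(precipitation_mm, temperature_c) {
  ifelse(temperature_c > 0, precipitation_mm / temperature_c, NA_real_)
}

#' Attach site climate and salinity to records
#'
#' Containing-cell lookup of the designated `annual_precipitation`,
#' `annual_mean_temperature` and `topsoil_salinity` layers at each record's
#' site, plus the Lang aridity index. Records whose temperature is not
#' positive get `NA` aridity with a warning.
#'
#' @param stack An [eco_stack()] containing the three designated layers.
#' @param records Occurrence tibble with coordinates.
#' @param precipitation_layer,temperature_layer,salinity_layer Layer names.
#' @return `records` with `annual_precipitation`, `annual_mean_temperature`,
#'   `topsoil_salinity` and `lang_aridity` columns (`NA` for records off
#'   the grid or on nodata).
#' @export
site_climate <- function(stack, records,
                         precipitation_layer = "annual_precipitation",
                         temperature_layer = "annual_mean_temperature",
                         salinity_layer = "topsoil_salinity") {
  need <- c(precipitation_layer, temperature_layer, salinity_layer)
  missing_l <- setdiff(need, names(stack$layers))
  if (length(missing_l)) {
    stop("stack lacks layer(s): ", paste(missing_l, collapse = ", "), call. = FALSE)
  }
  idx <- cell_index(stack, records$longitude, records$latitude)
  flat <- (idx$col - 1L) * stack$nrow + idx$row
  look <- function(layer) {
    as.vector(stack$layers[[layer]])[ifelse(is.na(flat), 1L, flat)] |>
      (\(v) ifelse(is.na(flat), NA_real_, v))()
  }
  records$annual_precipitation <- look(precipitation_layer)
  records$annual_mean_temperature <- look(temperature_layer)
  records$topsoil_salinity <- look(salinity_layer)
  bad_t <- !is.na(records$annual_mean_temperature) &
    records$annual_mean_temperature <= 0
  if (any(bad_t)) {
    rlang::warn(sprintf(
      "%d record(s) with non-positive annual mean temperature: aridity undefined",
      sum(bad_t)
    ))
  }
  records$lang_aridity <- lang_aridity_index(
    records$annual_precipitation, records$annual_mean_temperature
  )
  records
}

#' Filter records to arid sites
#'
#' Keeps records whose Lang aridity index is strictly below `threshold`
#' (default 40, the boundary between arid and humid site classes used for
#' drought-tolerance screening). Records with undefined aridity are
#' excluded.
#'
#' @param records Tibble with a `lang_aridity` column.
#' @param threshold Aridity cutoff.
#' @return The arid subset.
#' @export
filter_arid <- function(records, threshold = 40) {
  dplyr::filter(records, !is.na(.data$lang_aridity), .data$lang_aridity < threshold)
}

#' Per-species selection count under the top-fraction rule
#'
#' `round_half_up(fraction * n)` — the number of populations taken per
#' species when selecting the top salinity fraction of its arid priority
#' gaps.
#'
#' @param n_arid Number of arid priority-gap populations per species.
#' @param fraction Selected fraction (default 0.2).
#' @return Integer vector of selection counts.
#' @examples
#' pc_count_rule(c(10, 103, 76, 26, 8)) # 2 21 15 5 2
#' @export
pc_count_rule <- function(n_arid, fraction = 0.2) {
  as.integer(round_half_up(fraction * n_arid))
}

#' Select the top-salinity fraction per species
#'
#' From each species' arid priority-gap populations, selects
#' `round_half_up(fraction * n)` records by topsoil salinity descending;
#' ties are broken by Lang aridity ascending (more arid first), then record
#' id. These are the candidate collection sites for drought and salinity
#' tolerance.
#'
#' @param arid Arid records (from [filter_arid()]) with `species`,
#'   `topsoil_salinity`, `lang_aridity`, `record_id`.
#' @param fraction Fraction selected per species.
#' @return The selected records, with a `selected_rank` within species.
#' @export
select_top_salinity <- function(arid, fraction = 0.2) {
  arid |>
    dplyr::group_by(.data$species) |>
    dplyr::arrange(
      dplyr::desc(.data$topsoil_salinity), .data$lang_aridity,
      .data$record_id,
      .by_group = TRUE
    ) |>
    dplyr::mutate(selected_rank = dplyr::row_number()) |>
    dplyr::filter(.data$selected_rank <= pc_count_rule(dplyr::n(), fraction)) |>
    dplyr::ungroup()
}

#' Predictive-characterization report table
#'
#' One row per selected population: species, coordinates, administrative
#' units, Lang index (printed as an integer) and topsoil salinity (one
#' decimal), sorted by salinity descending.
#'
#' @param selected Output of [select_top_salinity()].
#' @return A tibble mirroring a collection-site shortlist.
#' @export
pc_report <- function(selected) {
  selected |>
    dplyr::transmute(
      species = .data$species,
      latitude = .data$latitude,
      longitude = .data$longitude,
      province = .data$adm2,
      municipality = .data$adm3,
      lang_index = as.integer(round_half_up(.data$lang_aridity)),
      topsoil_salinity = round(.data$topsoil_salinity, 1)
    ) |>
    dplyr::arrange(dplyr::desc(.data$topsoil_salinity), .data$lang_index)
}

#' Predictive characterization of priority gaps
#'
#' End-to-end drought/salinity screening: attach site climate to the
#' priority-gap records, keep sites with Lang aridity strictly below the
#' threshold, select the per-species top salinity fraction and build the
#' report.
#'
#' @param stack An [eco_stack()] with the designated climate/soil layers.
#' @param priority_records Priority ecogeographical gap records (all
#'   species).
#' @param aridity_threshold Lang-index cutoff.
#' @param fraction Per-species selected fraction.
#' @return A list with `climate` (priority records + climate columns),
#'   `arid`, `selected`, `report` (from [pc_report()]) and `counts`
#'   (per-species arid/selected counts).
#' @export
predictive_characterization <- function(stack, priority_records,
                                        aridity_threshold = 40,
                                        fraction = 0.2) {
  clim <- site_climate(stack, priority_records)
  arid <- filter_arid(clim, aridity_threshold)
  selected <- select_top_salinity(arid, fraction)
  counts <- arid |>
    dplyr::count(.data$species, name = "n_arid") |>
    dplyr::left_join(
      dplyr::count(selected, .data$species, name = "n_selected"),
      by = "species"
    ) |>
    dplyr::mutate(n_selected = tidyr::replace_na(.data$n_selected, 0L))
  list(
    climate = clim, arid = arid, selected = selected,
    report = pc_report(selected), counts = counts
  )
}
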