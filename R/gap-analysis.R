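#' Identify spatial gaps
#'
#' An external-source record is a spatial gap when it lies strictly more
#' than `threshold_km` (great-circle) from *every* genebank accession of
#' the same species. A species with no accessions has all its external
#' records as spatial gaps.
#'
#' @param records QC-passed occurrence tibble (both source classes, any
#'   number of species).
#' @param threshold_km Gap distance threshold in km.
#' @return The external records with a logical column `is_spatial_gap`.
#' @export
spatial_gaps <- function(records, threshold_km = 1.0) {
  ext <- dplyr::filter(records, .data$source_class == "external")
  acc <- dplyr::filter(records, .data$source_class == "accession")
  ext |>
    dplyr::group_by(.data$species) |>
    dplyr::group_modify(function(e, key) {
      a <- acc[acc$species == key$species, ]
      if (!nrow(a)) {
        e$is_spatial_gap <- TRUE
        return(e)
      }
      d <- haversine_cross(e$latitude, e$longitude, a$latitude, a$longitude)
      e$is_spatial_gap <- apply(d, 1, min) > threshold_km
      e
    }) |>
    dplyr::ungroup()
}

#' Ecogeographical representativeness of a collection
#'
#' For one species, compares the ELC categories covered by conserved
#' accessions against those where external sources report the species.
#' Categories holding at least one external record and no accession are the
#' ecogeographical gap categories. Records with category 0 (unassigned) are
#' excluded.
#'
#' @param elc The species' `elc_map`.
#' @param records Occurrence tibble with `source_class` and `elc_category`
#'   assigned (see [assign_category()]).
#' @return A `representativeness` object: `n_categories` (C of the map),
#'   `represented` (category ids with accessions), `gap_categories`,
#'   `freq` (per-category tibble of territory/accession/external record
#'   shares).
#' @export
representativeness <- function(elc, records) {
  rec <- dplyr::filter(records, .data$elc_category > 0)
  acc_cat <- rec$elc_category[rec$source_class == "accession"]
  ext_cat <- rec$elc_category[rec$source_class == "external"]
  cats <- elc$legend$category
  freq <- tibble::tibble(
    category = cats,
    territory_share = elc$legend$territory_share,
    accession_share = as.vector(table(factor(acc_cat, levels = cats))) /
      max(1L, length(acc_cat)),
    external_share = as.vector(table(factor(ext_cat, levels = cats))) /
      max(1L, length(ext_cat))
  )
  represented <- sort(unique(acc_cat))
  gap <- sort(setdiff(unique(ext_cat), represented))
  structure(
    list(
      n_categories = length(cats),
      represented = represented,
      gap_categories = gap,
      freq = freq
    ),
    class = "representativeness"
  )
}

#' @export
print.representativeness <- function(x, ...) {
  cat("<representativeness> ", length(x$represented), "/", x$n_categories,
    " categories represented; ", length(x$gap_categories),
    " gap categories\n",
    sep = ""
  )
  invisible(x)
}

#' Rank external records by collection priority
#'
#' Assigns each external record a collection-priority rank from 1 to 10.
#' Records in categories *unrepresented* by accessions get ranks 1-4: the
#' quartile index of their category's territory share among the
#' unrepresented categories, rarest first (ties take the lower, i.e.
#' higher-priority, rank). Records in represented categories get ranks
#' 5-10: `5 + min(5, floor(5 * accession share / external share))`, so a
#' category already over-collected relative to its reported occurrence
#' drifts to the bottom. Ranks 1-4 therefore coincide exactly with the
#' priority ecogeographical gaps (unrepresented categories). Records with
#' category 0 are not rankable and are dropped with a warning.
#'
#' @param records External-source records with `elc_category` assigned.
#' @param rep A `representativeness` object for the same species.
#' @return `records` (category > 0 only) with integer `priority_rank` and
#'   logical `is_priority_gap` (`rank <= 4`).
#' @export
priority_rank <- function(records, rep) {
  n_bad <- sum(records$elc_category == 0)
  if (n_bad > 0) {
    rlang::warn(sprintf("%d record(s) with category 0 are not rankable", n_bad))
  }
  rec <- dplyr::filter(records, .data$elc_category > 0)

  unrep <- setdiff(rep$freq$category, rep$represented)
  f_un <- rep$freq[rep$freq$category %in% unrep, ]
  quart <- integer(0)
  if (nrow(f_un)) {
    pos <- rank(f_un$territory_share, ties.method = "min")
    quart <- stats::setNames(
      pmax(1L, as.integer(ceiling(4 * pos / nrow(f_un)))), f_un$category
    )
  }
  fr <- rep$freq
  rk <- vapply(rec$elc_category, function(ct) {
    if (ct %in% unrep) {
      return(quart[[as.character(ct)]])
    }
    acc_s <- fr$accession_share[fr$category == ct]
    ext_s <- fr$external_share[fr$category == ct]
    5L + min(5L, as.integer(floor(5 * acc_s / ext_s)))
  }, integer(1))
  rec$priority_rank <- rk
  rec$is_priority_gap <- rk <= 4L
  rec
}

#' Representativeness improvement percentages
#'
#' Current representativeness and its potential improvement if all gap
#' categories were collected, as integer percentages of the map's category
#' count (round-half-up).
#'
#' @param n_categories Total ELC categories C in the map.
#' @param n_represented Categories currently holding accessions.
#' @param n_gap_categories Categories in the (priority) gaps.
#' @return A tibble with `current_pct` and `improvement_pct`.
#' @examples
#' improvement_stats(27, 13, 12) # 48% now, +44%
#' @export
improvement_stats <- function(n_categories, n_represented, n_gap_categories) {
  if (any(n_categories == 0)) stop("n_categories must be positive", call. = FALSE)
  if (any(n_represented + n_gap_categories > n_categories)) {
    stop("represented + gap categories cannot exceed the total", call. = FALSE)
  }
  tibble::tibble(
    current_pct = pct_int(n_represented, n_categories),
    improvement_pct = pct_int(n_gap_categories, n_categories)
  )
}

#' Per-species gap summary tables
#'
#' Builds the two report tables of a gap analysis from per-species ranked
#' external records: (a) counts of externals, spatial gaps and priority
#' ecogeographical gaps with the percentage of externals that are priority
#' gaps, plus a TOTAL row; (b) per-species representativeness: categories
#' in the map, currently represented, in the spatial and priority gaps,
#' and the current/improvement percentages.
#'
#' @param ranked Named list (by species) of ranked external tibbles from
#'   [priority_rank()], each also carrying `is_spatial_gap` from
#'   [spatial_gaps()].
#' @param reps Named list (by species) of `representativeness` objects.
#' @return A list of tibbles `gaps` and `representativeness`.
#' @export
gap_report <- function(ranked, reps) {
  per_sp <- purrr::imap(ranked, function(e, sp) {
    tibble::tibble(
      species = sp,
      n_external = nrow(e),
      n_spatial_gaps = sum(e$is_spatial_gap),
      n_priority_gaps = sum(e$is_priority_gap),
      pct_priority = pct_int(sum(e$is_priority_gap), nrow(e))
    )
  })
  gaps <- dplyr::bind_rows(per_sp)
  total <- tibble::tibble(
    species = "TOTAL",
    n_external = sum(gaps$n_external),
    n_spatial_gaps = sum(gaps$n_spatial_gaps),
    n_priority_gaps = sum(gaps$n_priority_gaps),
    pct_priority = NA_real_
  )
  gaps <- dplyr::bind_rows(gaps, total)

  rep_tbl <- purrr::imap(reps, function(r, sp) {
    e <- ranked[[sp]]
    spatial_cats <- sort(unique(e$elc_category[e$is_spatial_gap]))
    gap_cats <- sort(unique(e$elc_category[e$is_priority_gap]))
    imp <- improvement_stats(r$n_categories, length(r$represented), length(gap_cats))
    tibble::tibble(
      species = sp,
      n_categories = r$n_categories,
      n_represented = length(r$represented),
      pct_represented = imp$current_pct,
      n_spatial_gap_categories = length(spatial_cats),
      n_priority_gap_categories = length(gap_cats),
      pct_improvement = imp$improvement_pct
    )
  })
  list(gaps = gaps, representativeness = dplyr::bind_rows(rep_tbl))
}

#' Full gap analysis for a multi-species occurrence table
#'
#' Per species: assign ELC categories, find spatial gaps, compute
#' representativeness, rank externals, and summarize.
#'
#' @param elc_by_species Named list (by species) of `elc_map` objects.
#' @param records QC-passed, quality-passing occurrence tibble (all
#'   species, both source classes).
#' @param threshold_km Spatial-gap distance, km.
#' @return A list with `ranked` (per-species ranked externals), `reps`
#'   (per-species representativeness) and `report` (from [gap_report()]).
#' @export
analyze_gaps <- function(elc_by_species, records, threshold_km = 1.0) {
  species <- intersect(names(elc_by_species), unique(records$species))
  ranked <- list()
  reps <- list()
  for (sp in species) {
    rec <- dplyr::filter(records, .data$species == sp)
    rec <- assign_category(elc_by_species[[sp]], rec)
    ext <- spatial_gaps(rec, threshold_km)
    rp <- representativeness(elc_by_species[[sp]], rec)
    ranked[[sp]] <- priority_rank(ext, rp)
    reps[[sp]] <- rp
  }
  list(ranked = ranked, reps = reps, report = gap_report(ranked, reps))
}
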