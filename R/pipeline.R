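#' Pipeline configuration
#'
#' Collects every tunable of the gap-analysis workflow with the standard
#' defaults: quality pass mark > 80 (0-100 scale), 1 km duplicate and
#' spatial-gap distance, |r| > 0.50 with p < 0.05 correlation pruning
#' within the top 15 ranked variables, at most 8 K-means clusters per
#' ecogeographical component, 3 + 3 + 2 variables selected per component
#' (plus latitude/longitude), Lang aridity cutoff 40 and a 20% top-salinity
#' fraction.
#'
#' The `species` table defines the synthetic study: one row per species
#' with columns `species`, `n_accessions`, `n_external`, `n_withheld`
#' (number of true categories kept free of accessions), `dup_fraction`,
#' `degrade_fraction`.
#'
#' @param landscape A [landscape_spec()] describing the synthetic
#'   territory (or `NULL` when `stack`/`records` are supplied to
#'   [run_pipeline()] directly).
#' @param species Tibble of per-species sampling settings (see Details).
#' @param quality_threshold,distance_km,top_n,r_threshold,alpha,k_max,
#'   aridity_threshold,salinity_fraction,n_bioclimatic,n_edaphic,
#'   n_geophysic Workflow thresholds.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `pipeline_config` object (a list).
#' @export
pipeline_config <- function(landscape = landscape_spec(),
                            species = default_species_table(),
                            quality_threshold = 80,
                            distance_km = 1.0,
                            top_n = 15,
                            r_threshold = 0.50,
                            alpha = 0.05,
                            k_max = 8,
                            aridity_threshold = 40,
                            salinity_fraction = 0.2,
                            n_bioclimatic = 3,
                            n_edaphic = 3,
                            n_geophysic = 2,
                            seed = 1L) {
  structure(
    list(
      landscape = landscape, species = species,
      quality_threshold = quality_threshold, distance_km = distance_km,
      top_n = top_n, r_threshold = r_threshold, alpha = alpha,
      k_max = k_max, aridity_threshold = aridity_threshold,
      salinity_fraction = salinity_fraction,
      n_bioclimatic = n_bioclimatic, n_edaphic = n_edaphic,
      n_geophysic = n_geophysic, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Default synthetic study: five species at desk scale
#'
#' Five congeneric species whose record counts mirror the shape of a real
#' national collection — one rare species with a handful of accessions,
#' two intensively recorded ones — scaled down so the full pipeline runs
#' in seconds. Each species has one or two ELC categories withheld from
#' accessions (guaranteed ecogeographical gaps) and realistic rates of
#' injected duplicates and degraded coordinates.
#'
#' @return A tibble with one row per species.
#' @export
default_species_table <- function() {
  tibble::tibble(
    species = paste0("Synthetica sp", 1:5),
    n_accessions = c(6L, 60L, 20L, 80L, 12L),
    n_external = c(30L, 500L, 250L, 400L, 150L),
    n_withheld = c(2L, 1L, 2L, 1L, 1L),
    dup_fraction = 0.15,
    degrade_fraction = 0.25,
    accession_cluster_sd = 0.2
  )
}

#' Validate a pipeline configuration
#'
#' Checks value ranges and the species table without mutating anything,
#' and returns *all* violations, not just the first.
#'
#' @param config A [pipeline_config()].
#' @return Character vector of violations; empty when the config is valid.
#' @export
validate_config <- function(config) {
  errs <- character()
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  chk(
    is.numeric(config$quality_threshold) && config$quality_threshold >= 0 &&
      config$quality_threshold <= 100,
    "quality_threshold must be in [0, 100]"
  )
  chk(config$distance_km > 0, "distance_km must be positive")
  chk(config$top_n >= 1, "top_n must be >= 1")
  chk(
    config$r_threshold > 0 && config$r_threshold <= 1,
    "r_threshold must be in (0, 1]"
  )
  chk(config$alpha > 0 && config$alpha < 1, "alpha must be in (0, 1)")
  chk(config$k_max >= 1 && config$k_max <= 8, "k_max must be in 1..8")
  chk(config$aridity_threshold >= 0, "aridity_threshold must be >= 0")
  chk(
    config$salinity_fraction >= 0 && config$salinity_fraction <= 1,
    "salinity_fraction must be in [0, 1]"
  )
  chk(
    all(c("species", "n_accessions", "n_external") %in% names(config$species)),
    "species table needs species, n_accessions, n_external columns"
  )
  if (!is.null(config$landscape)) {
    ok <- tryCatch(
      {
        validate_landscape_spec(config$landscape)
        TRUE
      },
      error = function(e) FALSE
    )
    chk(ok, "landscape spec is invalid")
  }
  errs
}

#' Run the full gap-analysis pipeline
#'
#' Executes the workflow end to end on a synthetic landscape: generate
#' rasters and per-species occurrence tables, occurrence QC, per-species
#' variable selection, ELC map construction, spatial and ecogeographical
#' gap analysis with priority ranking, and predictive characterization of
#' the priority gaps for drought and salinity. All randomness derives from
#' the master seed, so a rerun with the same config reproduces every table
#' byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return A `report_bundle` list: `qc_table`, `selection_table`,
#'   `elc_legends`, `gap_table`, `representativeness_table`, `pc_counts`,
#'   `pc_table`, `pc_improvement`, plus `records`, `elc`, `gaps`, `pc`,
#'   `truth` and a `log` tibble echoing the parameters.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  errs <- validate_config(config)
  if (length(errs)) {
    stop("invalid config:\n  - ", paste(errs, collapse = "\n  - "), call. = FALSE)
  }

  stage_fail <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
        call. = FALSE
      )
    })
  }

  land <- stage_fail("simulate", generate_raster_stack(config$landscape))
  stack <- land$stack
  truth <- land$truth
  all_cats <- sort(unique(stats::na.omit(as.vector(truth$category))))

  occ <- stage_fail("simulate", {
    tabs <- purrr::pmap(config$species, function(species, n_accessions,
                                                 n_external, n_withheld = 1L,
                                                 dup_fraction = 0,
                                                 degrade_fraction = 0,
                                                 accession_cluster_sd = NULL,
                                                 ...) {
      sseed <- derive_seed(config$seed, paste0("occ_", species))
      set.seed(sseed)
      withheld <- sample(all_cats, min(n_withheld, length(all_cats) - 1L))
      sample_occurrences(
        truth, n_accessions, n_external,
        withheld_categories = withheld,
        dup_fraction = dup_fraction, degrade_fraction = degrade_fraction,
        accession_cluster_sd = accession_cluster_sd,
        species = species, seed = derive_seed(sseed, "draw")
      )
    })
    dplyr::bind_rows(tabs)
  })

  records <- stage_fail("qc", {
    qc_pipeline(parse_occurrences(occ),
      threshold_km = config$distance_km,
      quality_threshold = config$quality_threshold
    )
  })
  qc_table <- qc_report(records)
  passed <- dplyr::filter(records, .data$qc_status == "retained", .data$quality_pass)

  usable <- passed |>
    dplyr::count(.data$species, .data$source_class) |>
    tidyr::pivot_wider(
      names_from = "source_class", values_from = "n", values_fill = 0L
    )
  ok_species <- usable$species[
    (usable$accession %||% 0) >= 1 & (usable$external %||% 0) >= 1
  ]
  if (!length(ok_species)) {
    rlang::warn("no species with both accessions and externals after QC: empty report")
    return(empty_report_bundle(config))
  }

  selections <- list()
  elc <- list()
  legends <- list()
  for (sp in ok_species) {
    sp_rec <- dplyr::filter(passed, .data$species == sp)
    sel <- stage_fail(
      "select-vars",
      select_variables(stack, sp_rec,
        seed = derive_seed(config$seed, paste0("vars_", sp)),
        top_n = config$top_n, r_threshold = config$r_threshold,
        alpha = config$alpha, n_bioclimatic = config$n_bioclimatic,
        n_edaphic = config$n_edaphic, n_geophysic = config$n_geophysic
      )
    )
    selections[[sp]] <- sel
    fit <- stage_fail(
      "elc",
      build_elc_map(stack, sel$selection,
        seed = derive_seed(config$seed, paste0("elc_", sp)),
        k_max = config$k_max
      )
    )
    elc[[sp]] <- fit$elc
    legends[[sp]] <- dplyr::mutate(
      fit$elc$legend[, c(
        "category", "bioclimatic", "edaphic", "geophysic",
        "n_cells", "territory_share"
      )],
      species = sp, .before = 1
    )
  }

  gaps <- stage_fail(
    "gaps",
    analyze_gaps(elc, dplyr::filter(passed, .data$species %in% ok_species),
      threshold_km = config$distance_km
    )
  )

  priority <- dplyr::bind_rows(gaps$ranked) |>
    dplyr::filter(.data$is_priority_gap)
  pc <- stage_fail(
    "pc",
    predictive_characterization(stack, priority,
      aridity_threshold = config$aridity_threshold,
      fraction = config$salinity_fraction
    )
  )

  pc_improvement <- purrr::imap(gaps$reps, function(r, sp) {
    sel_cats <- sort(unique(pc$selected$elc_category[pc$selected$species == sp]))
    imp <- improvement_stats(r$n_categories, length(r$represented), length(sel_cats))
    tibble::tibble(
      species = sp,
      n_categories = r$n_categories,
      n_represented = length(r$represented),
      pct_represented = imp$current_pct,
      n_pc_selected = sum(pc$selected$species == sp),
      n_pc_categories = length(sel_cats),
      pct_improvement = imp$improvement_pct
    )
  }) |> dplyr::bind_rows()

  structure(
    list(
      qc_table = qc_table,
      selection_table = dplyr::bind_rows(purrr::imap(
        selections,
        ~ dplyr::mutate(.x$selection, species = .y, .before = 1)
      )),
      elc_legends = dplyr::bind_rows(legends),
      gap_table = gaps$report$gaps,
      representativeness_table = gaps$report$representativeness,
      pc_counts = pc$counts,
      pc_table = pc$report,
      pc_improvement = pc_improvement,
      records = records,
      elc = elc,
      gaps = gaps,
      pc = pc,
      truth = truth,
      stack = stack,
      log = config_echo(config)
    ),
    class = "report_bundle"
  )
}

config_echo <- function(config) {
  flat <- config[!(names(config) %in% c("landscape", "species"))]
  tibble::tibble(
    parameter = names(flat),
    value = as.character(unlist(flat))
  )
}

empty_report_bundle <- function(config) {
  structure(
    list(
      qc_table = tibble::tibble(), selection_table = tibble::tibble(),
      elc_legends = tibble::tibble(), gap_table = tibble::tibble(),
      representativeness_table = tibble::tibble(),
      pc_counts = tibble::tibble(), pc_table = tibble::tibble(),
      pc_improvement = tibble::tibble(), records = tibble::tibble(),
      elc = list(), gaps = NULL, pc = NULL, truth = NULL, stack = NULL,
      log = config_echo(config)
    ),
    class = "report_bundle"
  )
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  if (nrow(x$gap_table)) {
    cat("  species analysed:", nrow(x$gap_table) - 1, "\n")
    tot <- x$gap_table[x$gap_table$species == "TOTAL", ]
    cat(
      "  externals:", tot$n_external,
      "| spatial gaps:", tot$n_spatial_gaps,
      "| priority gaps:", tot$n_priority_gaps, "\n"
    )
    if (nrow(x$pc_table)) cat("  PC subset:", nrow(x$pc_table), "populations\n")
  } else {
    cat("  (empty report)\n")
  }
  invisible(x)
}

#' Write the report bundle as CSV files
#'
#' Writes every report table of the bundle to `dir` with stable names, so
#' a rerun under the same configuration produces byte-identical files.
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- c(
    "qc_table", "selection_table", "elc_legends", "gap_table",
    "representativeness_table", "pc_counts", "pc_table", "pc_improvement",
    "log"
  )
  for (tb in tabs) {
    readr::write_csv(bundle[[tb]], file.path(dir, paste0(tb, ".csv")), na = "")
  }
  invisible(dir)
}
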